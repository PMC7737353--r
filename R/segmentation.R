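# SSE helpers on possibly-NA standardized channels, via cumulative sums
channel_cumsums <- function(z) {
  v <- ifelse(is.na(z), 0, z)
  list(s = cumsum(v), s2 = cumsum(v^2), n = cumsum(!is.na(z)))
}

range_sse <- function(cs, i, j) {
  s <- cs$s[j] - if (i > 1) cs$s[i - 1] else 0
  s2 <- cs$s2[j] - if (i > 1) cs$s2[i - 1] else 0
  n <- cs$n[j] - if (i > 1) cs$n[i - 1] else 0
  if (n == 0) 0 else s2 - s^2 / n
}

# robust per-channel noise scale from successive differences
diff_scale <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) return(1)
  s <- stats::mad(diff(x)) / sqrt(2)
  if (s <= 0) 1e-6 else s
}

# binary segmentation on a two-channel standardized matrix, with a windowed
# two-breakpoint rescue scan for short interior segments whose single-split
# gain is diluted by long flanks
binseg <- function(z1, z2, min_probes, penalty, max_window = 250) {
  n <- length(z1)
  cs1 <- channel_cumsums(z1)
  cs2 <- channel_cumsums(z2)
  seg_cost <- function(i, j) range_sse(cs1, i, j) + range_sse(cs2, i, j)

  stats_of <- function(cs, i, j) {
    c(s = cs$s[j] - if (i > 1) cs$s[i - 1] else 0,
      s2 = cs$s2[j] - if (i > 1) cs$s2[i - 1] else 0,
      n = cs$n[j] - if (i > 1) cs$n[i - 1] else 0)
  }
  sse_of <- function(s, s2, n) ifelse(n > 0, s2 - s^2 / n, 0)

  # best interior window [k, k+L-1] cut out of [i, j]; complement pooled
  best_window <- function(i, j) {
    best <- list(gain = -Inf)
    tot1 <- stats_of(cs1, i, j)
    tot2 <- stats_of(cs2, i, j)
    total <- sse_of(tot1["s"], tot1["s2"], tot1["n"]) +
      sse_of(tot2["s"], tot2["s2"], tot2["n"])
    lens <- unique(round(min_probes * 1.5^(0:8)))
    lens <- lens[lens <= min((j - i + 1) - min_probes, max_window)]
    for (L in lens) {
      ks <- (i + 1):(j - L)   # window strictly interior
      if (length(ks) < 1) next
      win_gain <- function(cs, tot) {
        s <- cs$s[ks + L - 1] - cs$s[ks - 1]
        s2 <- cs$s2[ks + L - 1] - cs$s2[ks - 1]
        nn <- cs$n[ks + L - 1] - cs$n[ks - 1]
        sw <- sse_of(s, s2, nn)
        sco <- sse_of(tot["s"] - s, tot["s2"] - s2, tot["n"] - nn)
        list(sse = sw + sco)
      }
      g1 <- win_gain(cs1, tot1)
      g2 <- win_gain(cs2, tot2)
      gains <- total - (g1$sse + g2$sse)
      bi <- which.max(gains)
      if (gains[bi] > best$gain) {
        best <- list(gain = gains[bi], k = ks[bi], L = L)
      }
    }
    best
  }

  breaks <- integer(0)
  recurse <- function(i, j) {
    if (j - i + 1 < 2 * min_probes) return(invisible())
    ks <- (i + min_probes - 1):(j - min_probes)
    total <- seg_cost(i, j)
    gains <- vapply(ks, function(k) {
      total - seg_cost(i, k) - seg_cost(k + 1, j)
    }, 0)
    best <- which.max(gains)
    if (gains[best] > penalty) {
      k <- ks[best]
      breaks <<- c(breaks, k)
      recurse(i, k)
      recurse(k + 1, j)
      return(invisible())
    }
    if (j - i + 1 >= 3 * min_probes) {
      bw <- best_window(i, j)
      if (bw$gain > 2 * penalty) {
        k1 <- bw$k - 1
        k2 <- bw$k + bw$L - 1
        breaks <<- c(breaks, k1, k2)
        recurse(i, k1)
        recurse(k1 + 1, k2)
        recurse(k2 + 1, j)
      }
    }
    invisible()
  }
  recurse(1, n)
  sort(unique(breaks))
}

#' Segment an array track into piecewise-constant intervals
#'
#' Binary changepoint segmentation jointly on LRR and folded BAF
#' (`|BAF - 0.5|` of heterozygous-range probes), each channel standardized by
#' a robust noise estimate from successive probe differences. Deterministic
#' for a fixed input.
#'
#' @param track An `array_track` data frame (see [simulate_array()]).
#' @param min_probes Minimum probes per segment.
#' @param penalty Cost-reduction threshold for accepting a split; default
#'   `6 * log(n)` per chromosome (a conservative BIC-style penalty for a
#'   two-channel mean shift).
#' @param het_range BAF range within which a probe counts as heterozygous for
#'   the folded-BAF channel.
#' @return Data frame `chrom, start, end, first_probe, last_probe, n_probes`
#'   (bp intervals spanning the first to last probe of each segment).
#' @export
segment_tracks <- function(track, min_probes = 20, penalty = NULL,
                           het_range = c(0.1, 0.9)) {
  if (is.null(track) || nrow(track) < 2) stop("track must contain >= 2 probes")
  out <- list()
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$pos), , drop = FALSE]
    n <- nrow(tr)
    fold <- abs(tr$baf - 0.5)
    fold[is.na(tr$baf) | tr$baf < het_range[1] | tr$baf > het_range[2]] <- NA
    z1 <- tr$lrr / diff_scale(tr$lrr)
    z2 <- fold / diff_scale(fold)
    pen <- if (is.null(penalty)) 6 * log(n) else penalty
    br <- if (n >= 2 * min_probes) binseg(z1, z2, min_probes, pen) else integer(0)
    lo <- c(1, br + 1)
    hi <- c(br, n)
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, start = tr$pos[lo], end = tr$pos[hi],
      first_probe = lo, last_probe = hi, n_probes = hi - lo + 1,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
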