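#' Extract BAF band centers and weights from a track interval
#'
#' One-dimensional mode clustering of the BAF values in an interval: kernel
#' density peaks are kept greedily (highest first) subject to a minimum band
#' separation; probes are assigned to the nearest kept peak and band centers
#' are re-estimated as cluster means. Weights are probe shares.
#'
#' @param track An `array_track` data frame.
#' @param chrom,start,end Query interval.
#' @param min_sep Minimum separation between band centers.
#' @param max_bands Maximum number of bands returned (highest-weight kept).
#' @param bw Kernel bandwidth for peak finding.
#' @param min_probes Minimum probes required in the interval.
#' @return Data frame `center, weight` sorted by center.
#' @export
extract_baf_bands <- function(track, chrom, start, end, min_sep = 0.08,
                              max_bands = 6, bw = 0.015, min_probes = 10) {
  sel <- track$chrom == as.character(chrom) & track$pos >= start &
    track$pos <= end & !is.na(track$baf)
  x <- track$baf[sel]
  if (length(x) < min_probes) {
    stop("insufficient data: ", length(x), " informative probes in interval")
  }
  cluster_baf_values(x, min_sep = min_sep, max_bands = max_bands, bw = bw)
}

# core 1-D mode clustering used by extract_baf_bands and the bootstrap
cluster_baf_values <- function(x, min_sep = 0.08, max_bands = 6, bw = 0.015) {
  d <- stats::density(x, bw = bw, from = -0.05, to = 1.05, n = 512)
  y <- d$y
  peak <- which(diff(sign(diff(y))) == -2) + 1
  # include plateau edges at the truncation piles
  if (y[1] > y[2]) peak <- c(1, peak)
  if (y[512] > y[511]) peak <- c(peak, 512)
  if (length(peak) == 0) peak <- which.max(y)
  cand <- d$x[peak][order(y[peak], decreasing = TRUE)]
  kept <- numeric(0)
  for (p in cand) {
    if (all(abs(p - kept) >= min_sep)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  # assign probes to nearest peak, re-estimate centers as cluster means
  for (it in 1:3) {
    idx <- vapply(x, function(v) which.min(abs(v - kept)), 0L)
    centers <- vapply(seq_along(kept), function(k) {
      if (any(idx == k)) mean(x[idx == k]) else NA_real_
    }, 0)
    keep <- !is.na(centers)
    kept <- sort(centers[keep])
  }
  idx <- vapply(x, function(v) which.min(abs(v - kept)), 0L)
  w <- tabulate(idx, nbins = length(kept)) / length(x)
  bands <- data.frame(center = pmin(1, pmax(0, kept)), weight = w)
  bands <- bands[bands$weight > 0, , drop = FALSE]
  if (nrow(bands) > max_bands) {
    bands <- bands[order(bands$weight, decreasing = TRUE)[seq_len(max_bands)], ]
    bands <- bands[order(bands$center), , drop = FALSE]
  }
  rownames(bands) <- NULL
  bands
}
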