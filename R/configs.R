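# cache of enumeration tables keyed by (max_total, max_clones, step)
.config_cache <- new.env(parent = emptyenv())

# enumeration family: single-clone homologue dosages (a >= b, canonical up to
# label swap) plus two-clone pairs whose clones differ by a single-copy gain
# or loss of one homologue (one simple subclonal event; larger jumps are not
# identifiable from mixture bands and LRR, which constrain only the
# population-average dosage), over a fraction grid
config_family <- function(max_total = 12, max_clones = 2, step = 0.01) {
  key <- paste(max_total, max_clones, step)
  if (!is.null(.config_cache[[key]])) return(.config_cache[[key]])
  singles <- do.call(rbind, lapply(1:max_total, function(tot) {
    b <- 0:(tot %/% 2)
    data.frame(a1 = tot - b, b1 = b)
  }))
  tab <- data.frame(a1 = singles$a1, b1 = singles$b1, a2 = singles$a1,
                    b2 = singles$b1, f = 1, n_clones = 1L)
  if (max_clones >= 2) {
    pairs <- list()
    for (i in seq_len(nrow(singles))) {
      a <- singles$a1[i]; b <- singles$b1[i]
      va <- intersect(c(a - 1, a + 1), 0:(max_total - b))
      vb <- intersect(c(b - 1, b + 1), 0:(max_total - a))
      pa <- if (length(va)) data.frame(a1 = a, b1 = b, a2 = va, b2 = b)
      pb <- if (length(vb)) data.frame(a1 = a, b1 = b, a2 = a, b2 = vb)
      pairs[[i]] <- rbind(pa, pb)
    }
    pairs <- do.call(rbind, pairs)
    fs <- seq(step, 1 - step, by = step)
    two <- pairs[rep(seq_len(nrow(pairs)), each = length(fs)), ]
    two$f <- rep(fs, times = nrow(pairs))
    two$n_clones <- 2L
    tab <- rbind(tab, two)
  }
  rownames(tab) <- NULL
  .config_cache[[key]] <- tab
  tab
}

hom_like <- function(x) x <= 0.1 | x >= 0.9

# vectorised score of every row of a config family against observed bands
score_family <- function(tab, centers, weights, mean_lrr, lambda = 1,
                         hom_weight = 0.2, baseline_ploidy = 2, eps = 0.05) {
  wA <- tab$f * tab$a1 + (1 - tab$f) * tab$a2
  wB <- tab$f * tab$b1 + (1 - tab$f) * tab$b2
  wT <- wA + wB
  ok <- wT > 0
  h1 <- ifelse(ok, wA / wT, NA)
  h2 <- ifelse(ok, wB / wT, NA)
  wo <- weights * ifelse(hom_like(centers), hom_weight, 1)
  obs <- 0
  for (k in seq_along(centers)) {
    d2 <- pmin(centers[k]^2, (centers[k] - 1)^2,
               (centers[k] - h1)^2, (centers[k] - h2)^2)
    obs <- obs + wo[k] * d2
  }
  pred <- 0
  for (p in list(rep(0, nrow(tab)), rep(1, nrow(tab)), h1, h2)) {
    dmin <- Inf
    for (k in seq_along(centers)) dmin <- pmin(dmin, (p - centers[k])^2)
    u <- 0.25 * ifelse(hom_like(p), hom_weight, 1)
    pred <- pred + u * dmin
  }
  lrr_pred <- log2(pmax(eps, wT) / baseline_ploidy)
  sc <- obs + pred + lambda * (lrr_pred - mean_lrr)^2
  sc[!ok] <- Inf
  list(score = sc, wA = wA, wB = wB, wT = wT)
}

family_row_config <- function(tab, i, sc) {
  if (tab$n_clones[i] == 1L) {
    clones <- data.frame(nA = tab$a1[i], nB = tab$b1[i], f = 1)
  } else {
    clones <- data.frame(nA = c(tab$a1[i], tab$a2[i]),
                         nB = c(tab$b1[i], tab$b2[i]),
                         f = c(tab$f[i], 1 - tab$f[i]))
  }
  cfg <- allele_config(clones$nA, clones$nB, clones$f)
  structure(list(clones = clones, n_clones = tab$n_clones[i],
                 score = sc$score[i],
                 avg_dosage = c(sc$wA[i], sc$wB[i]),
                 cn_total = sc$wT[i],
                 expected_bands = baf_band_set(clones$nA, clones$nB,
                                               clones$f),
                 expected_lrr = expected_lrr(cfg)),
            class = "segment_config")
}

#' Enumerate allele configurations explaining a band/LRR observation
#'
#' Exhaustively scores one-clone homologue dosages `(n1, n2)` with
#' `n1 + n2 <= max_total` and two-clone configurations (clones differing by a
#' single homologue-dosage change, fractions on a grid) against observed BAF
#' band centers and mean LRR. The score is a weighted band SSE (homozygous
#' bands down-weighted, unmatched predicted bands penalised) plus
#' `lambda * (predicted - observed LRR)^2`; it is zero iff the predicted
#' bands and LRR match the observations exactly. Ties are broken by fewer
#' clones, then lower mean total copy number, then lexicographically.
#'
#' @param bands Data frame `center, weight` (see [extract_baf_bands()]).
#' @param mean_lrr Observed mean LRR of the segment.
#' @param max_total Maximum per-clone total copy number.
#' @param max_clones 1 or 2.
#' @param lambda LRR weight in the score.
#' @param step Fraction grid step for two-clone configurations.
#' @param tol Configurations scoring within `tol` of the best are reported
#'   as co-optimal (ambiguous).
#' @param hom_weight Down-weighting of homozygous (0/1) bands.
#' @param n_top Number of ranked configurations returned.
#' @param clone_penalty Additive parsimony margin charged to two-clone
#'   configurations, preventing a second clone from fitting band-center
#'   noise; a true mosaic improves the score by far more than this.
#' @param baseline_ploidy,eps LRR model parameters, see [expected_lrr()].
#' @return A `config_ranking`: list with `configs` (ranked
#'   `segment_config`s, best first), `ambiguous`, and `observed`.
#' @export
enumerate_configs <- function(bands, mean_lrr, max_total = 12,
                              max_clones = 2, lambda = 1, step = 0.01,
                              tol = 1e-6, hom_weight = 0.2, n_top = 10,
                              clone_penalty = 1e-3,
                              baseline_ploidy = 2, eps = 0.05) {
  if (max_total < 1 || max_clones < 1) stop("limits must be >= 1")
  if (is.null(bands) || nrow(bands) == 0) stop("bands must be non-empty")
  tab <- config_family(max_total, max_clones, step)
  sc <- score_family(tab, bands$center, bands$weight, mean_lrr,
                     lambda = lambda, hom_weight = hom_weight,
                     baseline_ploidy = baseline_ploidy, eps = eps)
  # parsimony margin: a second clone must buy a real score improvement
  sc$score <- sc$score + clone_penalty * (tab$n_clones - 1L)
  # quantize before ranking so float dust cannot decide ties
  scq <- round(sc$score, 8)
  wtq <- round(sc$wT, 6)
  # reduce two-clone pairs to their best fraction before ranking; mirrored
  # pairs (clone order swapped) share one canonical key
  swap <- tab$n_clones == 2L &
    (tab$a2 < tab$a1 | (tab$a2 == tab$a1 & tab$b2 < tab$b1))
  ka1 <- ifelse(swap, tab$a2, tab$a1); kb1 <- ifelse(swap, tab$b2, tab$b1)
  ka2 <- ifelse(swap, tab$a1, tab$a2); kb2 <- ifelse(swap, tab$b1, tab$b2)
  key <- paste(ka1, kb1, ka2, kb2, tab$n_clones)
  ord <- order(scq, tab$n_clones, wtq, ka1, kb1, ka2, kb2, tab$f)
  ord <- ord[!duplicated(key[ord])]
  best <- sc$score[ord[1]]
  n_tie <- sum(sc$score[ord] <= best + tol)
  take <- ord[seq_len(min(n_top, length(ord)))]
  configs <- lapply(take, function(i) family_row_config(tab, i, sc))
  structure(list(configs = configs, ambiguous = n_tie > 1,
                 observed = bands, mean_lrr = mean_lrr),
            class = "config_ranking")
}

#' @export
print.config_ranking <- function(x, ...) {
  cfg <- x$configs[[1]]
  cat(sprintf("<config_ranking> best score %.4g%s\n", cfg$score,
              if (x$ambiguous) " (ambiguous)" else ""))
  print(cfg$clones)
  invisible(x)
}

#' Population-average homologue dosage of a configuration
#'
#' @param config A `segment_config` (see [enumerate_configs()]).
#' @return Named vector `c(n_major, n_minor)` of the average copies of the
#'   more- and less-represented homologue (fractional under mosaicism), with
#'   attribute `ambiguous = TRUE` when the two are equal (balanced dosage
#'   cannot be assigned to a homologue).
#' @export
infer_homologue_dosage <- function(config) {
  d <- config$avg_dosage
  out <- c(n_major = max(d), n_minor = min(d))
  attr(out, "ambiguous") <- abs(d[1] - d[2]) < 1e-9
  out
}

#' Estimate the mosaic cell fraction of a two-clone segment
#'
#' Profiles the clone fraction on a grid, minimising the band score of the
#' selected two-clone configuration against the observed BAF bands plus the
#' LRR term (which carries all the fraction information when a segment has
#' lost one homologue and its bands sit at 0/1), with a probe-resampling
#' bootstrap confidence interval.
#'
#' @param track An `array_track`.
#' @param chrom,start,end Segment interval.
#' @param config A two-clone `segment_config` (from [enumerate_configs()]),
#'   or a `config_ranking` whose best configuration is two-clone.
#' @param step Fraction grid step.
#' @param n_boot Bootstrap resamples (0 disables the CI).
#' @param seed Integer seed for the bootstrap.
#' @param hom_weight,lambda As in [enumerate_configs()].
#' @param conf Confidence level of the percentile interval.
#' @return List `f` (estimated fraction of the configuration's first clone),
#'   `ci`, `boot` (bootstrap draws), `clones`.
#' @export
estimate_mosaic_fraction <- function(track, chrom, start, end, config,
                                     step = 0.01, n_boot = 200, seed = 1,
                                     hom_weight = 0.2, lambda = 1,
                                     conf = 0.95) {
  if (inherits(config, "config_ranking")) config <- config$configs[[1]]
  if (config$n_clones < 2) {
    stop("not applicable: the selected configuration has a single clone")
  }
  cl <- config$clones
  fs <- seq(0, 1, by = step)
  ftab <- data.frame(a1 = cl$nA[1], b1 = cl$nB[1], a2 = cl$nA[2],
                     b2 = cl$nB[2], f = fs, n_clones = 2L)
  fit_once <- function(bands, mean_lrr) {
    sc <- score_family(ftab, bands$center, bands$weight, mean_lrr,
                       lambda = lambda, hom_weight = hom_weight)
    fs[which.min(sc$score)]
  }
  sel <- which(track$chrom == as.character(chrom) & track$pos >= start &
                 track$pos <= end & !is.na(track$baf))
  x <- track$baf[sel]
  lr <- track$lrr[sel]
  f_hat <- fit_once(cluster_baf_values(x), mean(lr))
  ci <- NULL
  boot <- numeric(0)
  if (n_boot > 0) {
    boot <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      bi <- sample(seq_along(x), replace = TRUE)
      fit_once(cluster_baf_values(x[bi]), mean(lr[bi]))
    }, 0))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  }
  list(f = f_hat, ci = ci, boot = boot, clones = cl)
}
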