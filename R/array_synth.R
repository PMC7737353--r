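# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Construct an allele configuration
#'
#' Per-clone allele copy numbers for one genomic segment: each clone carries
#' `nA` copies of the A allele and `nB` of the B allele at a heterozygous
#' site, with cell fraction `f`.
#'
#' @param nA,nB Integer allele copy numbers per clone (vectors of equal
#'   length).
#' @param f Clone fractions, summing to 1.
#' @return Object of class `allele_config`.
#' @export
allele_config <- function(nA, nB, f = 1) {
  stopifnot(length(nA) == length(nB), length(f) == length(nA),
            all(nA >= 0), all(nB >= 0), abs(sum(f) - 1) < 1e-9)
  structure(list(nA = as.numeric(nA), nB = as.numeric(nB),
                 f = as.numeric(f)), class = "allele_config")
}

#' Expected B-allele frequency of a clone mixture
#'
#' The signal-weighted mixture BAF: `sum(f * nB) / sum(f * (nA + nB))`.
#'
#' @param config An [allele_config()].
#' @return Expected BAF in \[0, 1\].
#' @export
expected_baf <- function(config) {
  tot <- sum(config$f * (config$nA + config$nB))
  if (tot <= 0) stop("BAF undefined: mixture total copy number is zero")
  sum(config$f * config$nB) / tot
}

#' Expected log R ratio of a clone mixture
#'
#' `log2(max(eps, mean total copy number) / baseline_ploidy)`. The baseline
#' ploidy defaults to 2 (diploid reference) even for near-triploid genomes,
#' matching the convention of writing karyotypes from diploidy.
#'
#' @param config An [allele_config()].
#' @param baseline_ploidy Reference copy number mapping to LRR 0.
#' @param eps Floor applied to the mixture copy number before the log.
#' @return Expected LRR.
#' @export
expected_lrr <- function(config, baseline_ploidy = 2, eps = 0.05) {
  tot <- sum(config$f * (config$nA + config$nB))
  log2(max(eps, tot) / baseline_ploidy)
}

#' Expected BAF band set for per-homologue dosages
#'
#' Enumerates the four founder genotype classes of a biallelic SNP
#' (homozygous A, homozygous B, heterozygous with the B allele on homologue
#' one, heterozygous with B on homologue two) and returns the deduplicated,
#' sorted expected BAF of each class under the clone mixture.
#'
#' @param dos_a,dos_b Per-clone copy numbers of homologue one / homologue two.
#' @param f Clone fractions, summing to 1.
#' @param tol Deduplication tolerance.
#' @return Sorted numeric vector of at most 4 expected bands.
#' @export
baf_band_set <- function(dos_a, dos_b, f = 1, tol = 1e-9) {
  stopifnot(length(dos_a) == length(dos_b), all(dos_a >= 0), all(dos_b >= 0))
  tot <- dos_a + dos_b
  bands <- c(
    expected_baf(allele_config(tot, rep(0, length(f)), f)),      # hom A
    expected_baf(allele_config(dos_b, dos_a, f)),                # B on hom 1
    expected_baf(allele_config(dos_a, dos_b, f)),                # B on hom 2
    expected_baf(allele_config(rep(0, length(f)), tot, f)))      # hom B
  bands <- sort(bands)
  bands[c(TRUE, diff(bands) > tol)]
}

#' Simulate a SNP probe panel
#'
#' Probes are placed uniformly at random along each chromosome, excluding the
#' centromere interval (arrays carry no probes there), and sorted by
#' position. Each probe has a population B-allele frequency used for founder
#' genotype drawing.
#'
#' @param map A [genome_map()].
#' @param density_per_mb Expected probes per Mb.
#' @param seed Integer seed; the panel is reproducible.
#' @return Data frame `probe, chrom, pos, pop_freq` of class `snp_panel`.
#' @export
make_probe_panel <- function(map, density_per_mb = 30, seed = 1) {
  stopifnot(density_per_mb > 0)
  with_seed(seed, {
    out <- lapply(seq_len(nrow(map)), function(i) {
      len <- map$length[i]
      n <- round(density_per_mb * len / 1e6)
      pos <- sort(round(runif(n, 1, len)))
      keep <- pos < map$cen_start[i] | pos > map$cen_end[i]
      pos <- unique(pos[keep])
      data.frame(probe = paste0("p", map$chrom[i], "_", pos),
                 chrom = map$chrom[i], pos = pos,
                 pop_freq = runif(length(pos), 0.05, 0.95),
                 stringsAsFactors = FALSE)
    })
    panel <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    class(panel) <- c("snp_panel", "data.frame")
    panel
  })
}

#' Draw founder genotypes for a probe panel
#'
#' One biallelic genotype per homologue haplotype per probe; all founder
#' copies descending from the same homologue (e.g. the two post-duplication
#' copies) share the haplotype, so they are genotype-identical by
#' construction.
#'
#' @param panel A [make_probe_panel()] panel.
#' @param seed Integer seed.
#' @return Data frame `probe, chrom, pos, b_on_a, b_on_b` (logicals: B allele
#'   carried by homologue "a" / "b").
#' @export
assign_genotypes <- function(panel, seed = 1) {
  with_seed(seed, {
    data.frame(probe = panel$probe, chrom = panel$chrom, pos = panel$pos,
               b_on_a = runif(nrow(panel)) < panel$pop_freq,
               b_on_b = runif(nrow(panel)) < panel$pop_freq,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a noisy SNP-array track for a cell population
#'
#' Per probe, the expected BAF and LRR are computed from the population's
#' homologue dosage at the probe position and the founder genotypes, then
#' independent Gaussian noise is added (BAF truncated to \[0, 1\]). With zero
#' noise the track equals the closed-form expectations exactly. Probes falling
#' in regions absent from every cell get BAF `NA`.
#'
#' @param pop A [cell_population()].
#' @param panel A [make_probe_panel()] panel.
#' @param genotypes Output of [assign_genotypes()] for `panel`.
#' @param sigma_baf,sigma_lrr Gaussian noise standard deviations.
#' @param seed Integer seed.
#' @param baseline_ploidy,eps As in [expected_lrr()].
#' @return Data frame `probe, chrom, pos, lrr, baf` of class `array_track`.
#' @export
simulate_array <- function(pop, panel, genotypes, sigma_baf = 0.03,
                           sigma_lrr = 0.15, seed = 1, baseline_ploidy = 2,
                           eps = 0.05) {
  stopifnot(sigma_baf >= 0, sigma_lrr >= 0,
            identical(panel$probe, genotypes$probe))
  eff <- effective_clones(pop)
  num <- numeric(nrow(panel))
  den <- numeric(nrow(panel))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    pos <- panel$pos[idx]
    ba <- genotypes$b_on_a[idx]
    bb <- genotypes$b_on_b[idx]
    for (e in eff) {
      d <- point_dosage(e$karyotype, ch, pos)
      num[idx] <- num[idx] + e$fraction * (d$a * ba + d$b * bb)
      den[idx] <- den[idx] + e$fraction * (d$a + d$b)
    }
  }
  baf <- ifelse(den > 0, num / den, NA_real_)
  lrr <- log2(pmax(eps, den) / baseline_ploidy)
  with_seed(seed, {
    if (sigma_lrr > 0) lrr <- lrr + rnorm(length(lrr), 0, sigma_lrr)
    if (sigma_baf > 0) {
      baf <- pmin(1, pmax(0, baf + rnorm(length(baf), 0, sigma_baf)))
    }
  })
  track <- data.frame(probe = panel$probe, chrom = panel$chrom,
                      pos = panel$pos, lrr = lrr, baf = baf,
                      stringsAsFactors = FALSE)
  class(track) <- c("array_track", "data.frame")
  track
}

#' Write / read an array track as TSV
#' @param track An `array_track` data frame.
#' @param path File path.
#' @export
write_track <- function(track, path) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  track <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = c(probe = "character",
                                            chrom = "character"))
  class(track) <- c("array_track", "data.frame")
  track
}
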