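test_that("expected BAF follows the signal-weighted mixture formula", {
  expect_equal(expected_baf(allele_config(2, 1)), 1 / 3)
  expect_equal(expected_baf(allele_config(c(2, 2), c(1, 0), c(2 / 3, 1 / 3))),
               0.25)
  expect_error(expected_baf(allele_config(c(0, 0), c(0, 0), c(0.5, 0.5))),
               "undefined")
  # A/B swap symmetry over random configurations
  set.seed(7)
  for (i in 1:30) {
    n <- sample(1:3, 1)
    nA <- sample(0:6, n, replace = TRUE)
    nB <- sample(0:6, n, replace = TRUE)
    if (sum(nA + nB) == 0) nA[1] <- 1
    f <- as.vector(stats::rmultinom(1, 100, rep(1, n))) / 100
    b <- expected_baf(allele_config(nA, nB, f))
    expect_equal(expected_baf(allele_config(nB, nA, f)), 1 - b)
    expect_gte(b, 0); expect_lte(b, 1)
  }
})

test_that("expected LRR is log2 of mixture copy number over baseline", {
  expect_equal(expected_lrr(allele_config(1, 1)), 0)
  expect_equal(expected_lrr(allele_config(2, 1)), log2(1.5))
  mix <- allele_config(c(2, 2), c(1, 2), c(0.5, 0.5))
  expect_equal(expected_lrr(mix), log2(1.75))
  expect_equal(expected_lrr(allele_config(0, 0), eps = 0.05), log2(0.025))
})

test_that("band sets enumerate genotype classes, deduplicated and symmetric", {
  expect_equal(baf_band_set(1, 1), c(0, 0.5, 1))
  expect_equal(baf_band_set(c(2, 2), c(1, 0), c(2 / 3, 1 / 3)),
               c(0, 0.25, 0.75, 1))
  # the amplified-state mixture: average dosage 2:6 gives the same bands
  expect_equal(baf_band_set(c(2, 2), c(1, 11), c(0.5, 0.5)),
               c(0, 0.25, 0.75, 1))
  set.seed(8)
  for (i in 1:30) {
    a <- sample(0:5, 2, replace = TRUE)
    b <- sample(0:5, 2, replace = TRUE)
    if (sum(a + b) == 0) a[1] <- 1
    f <- c(0.4, 0.6)
    bs <- baf_band_set(a, b, f)
    expect_lte(length(bs), 4)
    expect_equal(sort(1 - baf_band_set(b, a, f)), bs)  # symmetric about 0.5
  }
})

test_that("probe panels are reproducible, dense and centromere-free", {
  map <- genome_map(chromosomes = c("19", "20"))
  p1 <- make_probe_panel(map, 10, seed = 5)
  p2 <- make_probe_panel(map, 10, seed = 5)
  expect_identical(p1, p2)
  expected_n <- 10 * sum(map$length) / 1e6
  expect_lt(abs(nrow(p1) - expected_n) / expected_n, 0.15)
  for (i in seq_len(nrow(map))) {
    inside <- p1$chrom == map$chrom[i] & p1$pos >= map$cen_start[i] &
      p1$pos <= map$cen_end[i]
    expect_equal(sum(inside), 0)
  }
  expect_true(all(p1$pop_freq > 0 & p1$pop_freq < 1))
})

test_that("noiseless tracks equal closed-form expectations", {
  pop <- fixture_pop()
  map20 <- genome_map(chromosomes = "20")
  panel <- make_probe_panel(map20, 10, seed = 31)
  geno <- assign_genotypes(panel, seed = 32)
  tr <- simulate_array(pop, panel, geno, sigma_baf = 0, sigma_lrr = 0,
                       seed = 33)
  # 20q12 region is LOH: every informative probe is homozygous
  sel <- tr$pos >= 40e6 & tr$pos <= 48e6
  expect_true(all(tr$baf[sel] %in% c(0, 1)))
  expect_equal(unique(round(tr$lrr[sel], 6)), 0)  # CN2
  # per-probe exactness against the dosage/genotype arithmetic at 4 copies
  sel2 <- which(tr$pos >= 1e6 & tr$pos <= 7e6)    # 20p tip: 4 copies (2a,2b)
  het <- sel2[geno$b_on_a[sel2] != geno$b_on_b[sel2]]
  expect_true(all(abs(tr$baf[het] - 0.5) < 1e-12))
  expect_equal(unique(round(tr$lrr[sel2], 6)), 1) # log2(4/2)
})

test_that("noise model is Gaussian with the requested sd and truncation", {
  map <- genome_map(chromosomes = "1")
  kt <- toy_karyotype(map, "1")
  pop <- cell_population(list(clone(kt, 1)))
  panel <- make_probe_panel(map, 50, seed = 41)
  geno <- assign_genotypes(panel, seed = 42)
  tr <- simulate_array(pop, panel, geno, sigma_baf = 0.03, sigma_lrr = 0.15,
                       seed = 43)
  het <- geno$b_on_a != geno$b_on_b
  expect_gt(sum(het), 1e3)
  expect_lt(abs(sd(tr$baf[het]) - 0.03), 0.003)
  expect_lt(abs(mean(tr$baf[het]) - 0.5), 0.003)
  expect_lt(abs(sd(tr$lrr) - 0.15), 0.01)
  expect_true(all(tr$baf >= 0 & tr$baf <= 1))
  # determinism
  tr2 <- simulate_array(pop, panel, geno, sigma_baf = 0.03,
                        sigma_lrr = 0.15, seed = 43)
  expect_identical(tr, tr2)
})

test_that("mixture BAF agrees with pooled signal over simulated single cells", {
  cfg <- allele_config(c(2, 2), c(1, 0), c(0.7, 0.3))
  set.seed(99)
  n <- 1e5
  which_clone <- sample(1:2, n, replace = TRUE, prob = cfg$f)
  bsig <- cfg$nB[which_clone]
  tsig <- cfg$nA[which_clone] + cfg$nB[which_clone]
  est <- sum(bsig) / sum(tsig)
  se <- sd(bsig / mean(tsig)) / sqrt(n)   # delta-method scale
  expect_lt(abs(est - expected_baf(cfg)), 3 * se + 1e-4)
})

test_that("tracks round-trip through TSV", {
  map <- genome_map(chromosomes = "21")
  kt <- toy_karyotype(map, "21")
  pop <- cell_population(list(clone(kt, 1)))
  panel <- make_probe_panel(map, 5, seed = 51)
  tr <- simulate_array(pop, panel, assign_genotypes(panel, seed = 52),
                       seed = 53)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, path)
  tr2 <- read_track(path)
  expect_equal(tr2$probe, tr$probe)
  expect_equal(tr2$baf, tr$baf, tolerance = 1e-12)
  expect_equal(tr2$lrr, tr$lrr, tolerance = 1e-12)
})
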