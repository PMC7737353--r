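test_that("segmentation finds forced changepoints and nothing else", {
  map <- genome_map(chromosomes = "19")
  kt <- toy_karyotype(map, "19")
  pop_flat <- cell_population(list(clone(kt, 1)))
  panel <- make_probe_panel(map, 30, seed = 61)
  geno <- assign_genotypes(panel, seed = 62)
  tr_flat <- simulate_array(pop_flat, panel, geno, seed = 63)
  segs <- segment_tracks(tr_flat)
  expect_equal(nrow(segs), 1)       # constant track: single interval

  # one interstitial deletion: exactly three intervals, breakpoints at
  # probe resolution (+/- 2 probes)
  del <- rearrangement_event("deletion", member = "19.b1", chrom = "19",
                             start = 30e6, end = 40e6)
  pop_del <- cell_population(list(clone(apply_event(kt, del, map), 1)))
  tr_del <- simulate_array(pop_del, panel, geno, seed = 63)
  segs <- segment_tracks(tr_del)
  expect_equal(nrow(segs), 3)
  spacing <- 58.6e6 / nrow(tr_del)
  expect_lt(abs(segs$start[2] - 30e6), 4 * spacing)
  expect_lt(abs(segs$end[2] - 40e6), 4 * spacing)
  expect_error(segment_tracks(tr_del[0, ]), "2 probes")
})

test_that("the simulated fixture chromosome 6 yields its six states", {
  tr <- fixture_chr6_track()
  calls <- call_segments(tr, max_total = 14)
  tab <- calls$table
  expect_equal(nrow(tab), 6)
  truth_bp <- c(26e6, 34e6, 36e6, 48e6, 165e6)
  spacing <- 170.8e6 / nrow(tr)
  # clear copy-number steps localise to a few probes; the last boundary is a
  # 0.2-copy mosaic step and localises more loosely
  slack <- c(3, 3, 3, 3, 15) * spacing
  for (k in seq_along(truth_bp)) {
    expect_lt(abs(tab$start[k + 1] - truth_bp[k]), slack[k])
  }
  expect_equal(tab$cn_total, c(2, 3, 8, 4, 3.5, 3.7), tolerance = 0.05)
  expect_equal(tab$n_major, c(1, 2, 6, 2, 2, 2), tolerance = 0.05)
  expect_equal(tab$n_minor, c(1, 1, 2, 2, 1.5, 1.7), tolerance = 0.06)
  expect_equal(tab$mosaic_f[5], 0.5, tolerance = 0.03)
})

test_that("band extraction recovers diploid, LOH and mosaic band sets", {
  map <- genome_map(chromosomes = "19")
  panel <- make_probe_panel(map, 30, seed = 71)
  geno <- assign_genotypes(panel, seed = 72)
  kt <- toy_karyotype(map, "19")
  pop <- cell_population(list(clone(kt, 1)))
  tr <- simulate_array(pop, panel, geno, seed = 73)
  b <- extract_baf_bands(tr, "19", 1, 58e6)
  expect_equal(nrow(b), 3)
  expect_lt(max(abs(b$center - c(0, 0.5, 1))), 0.02)

  # LOH with two copies: bands at 0 and 1 only
  kt_loh <- karyotype("loh", list(
    normal_chromosome(map, "19", "a", "a1", name = "19.a1"),
    normal_chromosome(map, "19", "a", "a2", name = "19.a2")))
  tr2 <- simulate_array(cell_population(list(clone(kt_loh, 1))), panel,
                        geno, seed = 74)
  b2 <- extract_baf_bands(tr2, "19", 1, 58e6)
  expect_equal(nrow(b2), 2)
  expect_lt(max(abs(b2$center - c(0, 1))), 0.02)

  # three copies with one deleted in a third of cells
  kt3 <- apply_event(kt, rearrangement_event(
    "chromosome_gain", member = "19.a1", new_name = "19.a2",
    founder_suffix = "2"), map)
  pop3 <- cell_population(
    list(clone(kt3, 1)),
    submosaics = list(list(member = "19.b1", fraction = 1 / 3,
                           event = rearrangement_event(
                             "deletion", member = "19.b1", chrom = "19",
                             start = 1, end = 58617616))))
  tr3 <- simulate_array(pop3, panel, geno, seed = 75)
  b3 <- extract_baf_bands(tr3, "19", 1, 58e6)
  expect_equal(nrow(b3), 4)
  expect_lt(max(abs(b3$center - c(0, 0.25, 0.75, 1))), 0.02)

  expect_error(extract_baf_bands(tr, "19", 1, 2e5), "insufficient")
})

test_that("config enumeration identifies clean states and mosaics", {
  b_dip <- data.frame(center = c(0, 0.5, 1), weight = c(0.25, 0.5, 0.25))
  rk <- enumerate_configs(b_dip, 0)
  expect_equal(rk$configs[[1]]$clones, data.frame(nA = 1, nB = 1, f = 1))
  expect_false(rk$ambiguous)
  expect_equal(rk$configs[[1]]$score, 0)

  # CN 8/3 with bands 0/0.25/0.75/1: three copies, one deleted in 1/3
  b_mos <- data.frame(center = c(0, 0.25, 0.75, 1), weight = rep(0.25, 4))
  rk2 <- enumerate_configs(b_mos, log2(8 / 3 / 2))
  cfg <- rk2$configs[[1]]
  expect_equal(cfg$n_clones, 2)
  expect_equal(sort(cfg$clones$nA + cfg$clones$nB), c(2, 3))
  f_del <- cfg$clones$f[which.min(cfg$clones$nA + cfg$clones$nB)]
  expect_equal(f_del, 1 / 3, tolerance = 0.011)
  expect_error(enumerate_configs(b_dip, 0, max_total = 0), "limits")
})

test_that("noiseless single-clone states with distinct signatures rank first", {
  for (tot in 1:8) {
    for (b in 0:(tot %/% 2)) {
      a <- tot - b
      bands <- baf_band_set(a, b)
      w <- rep(1 / length(bands), length(bands))
      rk <- enumerate_configs(data.frame(center = bands, weight = w),
                              expected_lrr(allele_config(a, b)))
      cfg <- rk$configs[[1]]
      expect_equal(cfg$n_clones, 1, info = paste(a, b))
      expect_equal(unname(cfg$avg_dosage), sort(c(a, b), decreasing = TRUE),
                   info = paste(a, b))
      expect_equal(cfg$score, 0, tolerance = 1e-12)
    }
  }
})

test_that("mosaic fraction estimation matches truth and the grid oracle", {
  map <- genome_map(chromosomes = "20")
  panel <- make_probe_panel(map, 30, seed = 81)
  geno <- assign_genotypes(panel, seed = 82)
  kt <- toy_karyotype(map, "20")
  kt3 <- apply_event(kt, rearrangement_event(
    "chromosome_gain", member = "20.a1", new_name = "20.a2",
    founder_suffix = "2"), map)
  pop <- cell_population(
    list(clone(kt3, 1)),
    submosaics = list(list(member = "20.b1", fraction = 0.30,
                           event = rearrangement_event(
                             "deletion", member = "20.b1", chrom = "20",
                             start = 1, end = 64444167))))
  tr <- simulate_array(pop, panel, geno, seed = 83)
  calls <- call_segments(tr)
  expect_equal(nrow(calls$table), 1)
  expect_equal(calls$table$mosaic_f, 0.30, tolerance = 0.05)

  # the estimator is an exact grid search of its own objective
  cfg <- calls$details[[1]]$configs[[1]]
  est <- estimate_mosaic_fraction(tr, "20", calls$table$start,
                                  calls$table$end, cfg, n_boot = 50,
                                  seed = 9)
  expect_true(est$f %in% seq(0, 1, 0.01))
  expect_true(est$ci[1] <= est$f && est$f <= est$ci[2])
  grid_scores <- vapply(seq(0, 1, 0.01), function(f) {
    sel <- tr$pos >= calls$table$start & tr$pos <= calls$table$end
    bands <- extract_baf_bands(tr, "20", calls$table$start, calls$table$end)
    cl <- cfg$clones
    mix <- allele_config(cl$nA, cl$nB, c(f, 1 - f))
    hw <- ifelse(bands$center <= 0.1 | bands$center >= 0.9, 0.2, 1)
    preds <- c(0, 1, expected_baf(allele_config(cl$nB, cl$nA, c(f, 1 - f))),
               expected_baf(mix))
    obs <- sum(bands$weight * hw *
                 vapply(bands$center,
                        function(cc) min((cc - preds)^2), 0))
    pr <- sum(0.25 * ifelse(preds <= 0.1 | preds >= 0.9, 0.2, 1) *
                vapply(preds, function(p) min((p - bands$center)^2), 0))
    lrrterm <- (expected_lrr(mix) - mean(tr$lrr[sel]))^2
    obs + pr + lrrterm
  }, 0)
  expect_equal(est$f, seq(0, 1, 0.01)[which.min(grid_scores)])

  # a single-clone selection refuses a mosaic estimate
  flat <- simulate_array(cell_population(list(clone(kt, 1))), panel, geno,
                         seed = 84)
  fc <- call_segments(flat)
  expect_error(estimate_mosaic_fraction(flat, "20", 1, 6e7,
                                        fc$details[[1]]),
               "not applicable")
})

test_that("homologue dosage summarises configurations with conservation", {
  cfg <- enumerate_configs(
    data.frame(center = c(0, 0.25, 0.75, 1), weight = rep(0.25, 4)),
    log2(8 / 2))$configs[[1]]
  d <- infer_homologue_dosage(cfg)
  expect_equal(unname(c(d)), c(6, 2))
  expect_false(attr(d, "ambiguous"))
  expect_equal(sum(d), cfg$cn_total)

  dip <- enumerate_configs(
    data.frame(center = c(0, 0.5, 1), weight = c(0.25, 0.5, 0.25)),
    0)$configs[[1]]
  dd <- infer_homologue_dosage(dip)
  expect_equal(unname(c(dd)), c(1, 1))
  expect_true(attr(dd, "ambiguous"))
})
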