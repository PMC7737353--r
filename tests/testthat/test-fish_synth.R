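test_that("locus FISH reproduces the chromosome 11/16/20 reference table", {
  kt <- fixture_stemline()
  map <- fixture_map()
  ref <- u937_fish_reference()
  probes <- u937_fish_probes()
  tab <- fish_table(probes[match(ref$probe, probes$name), ], kt, map,
                    c("der(11)t(11;16;20)", "der(20)t(15;20)"))
  expect_equal(tab[["der(11)t(11;16;20)"]], ref$der11)
  expect_equal(tab[["der(20)t(15;20)"]], ref$der20)
})

test_that("probes straddling breakpoints give reduced signals", {
  kt <- fixture_stemline()
  map <- fixture_map()
  # RP11-185I4 straddles the larger 5q11.2 deletion breakpoint: reduced on
  # the deleted derivative (sub-mosaic clone), full elsewhere
  pop <- fixture_pop()
  eff <- effective_clones(pop)
  del_kt <- NULL
  for (e in eff) {
    m <- e$karyotype$members[["der(5)t(5;13)"]]
    if (min(m$segments$start[m$segments$chrom == "5"]) < 2 &&
        !any(m$segments$chrom == "5" & m$segments$start <= 50768911 &
               m$segments$end >= 50961846)) {
      del_kt <- e$karyotype
    }
  }
  expect_false(is.null(del_kt))
  pr <- u937_fish_probes()
  res <- simulate_locus_fish(pr[pr$name == "RP11-185I4", ], del_kt, map)
  expect_equal(res$symbol[res$member == "der(5)t(5;13)"], "(+)")
  # material fully absent scores an en dash
  res2 <- simulate_locus_fish(pr[pr$name == "RP11-317O24", ], del_kt, map)
  expect_equal(res2$symbol[res2$member == "der(5)t(5;13)"], "–")
})

test_that("centromere FISH counts chromosomes carrying the centromere", {
  kt <- fixture_stemline()
  map <- fixture_map()
  r11 <- simulate_centromere_fish("11", kt, map)
  expect_setequal(r11$member[r11$copies > 0],
                  c("11.a1", "der(11)t(10;11)", "der(11)t(11;16;20)"))
  r20 <- simulate_centromere_fish("20", kt, map)
  expect_equal(r20$copies[r20$member == "der(11)t(11;16;20)"], 0)
  expect_equal(r20$copies[r20$member == "der(20)t(15;20)"], 1)
  # a chromosome absent from the karyotype lights nothing up
  toy <- toy_karyotype(chroms = "1")
  expect_equal(sum(simulate_centromere_fish("2", toy, map)$copies), 0)
  # the inactive 1 centromere on the pseudodicentric is still hybridised
  r1 <- simulate_centromere_fish("1", kt, map)
  psu <- r1[r1$member == "psu dic(3;1)(q25.1;p11.1)", ]
  expect_equal(psu$copies, 1)
  expect_equal(psu$active, 0)
})

test_that("summed locus copy-equivalents equal the karyotype copy number", {
  kt <- fixture_stemline()
  map <- fixture_map()
  pop1 <- cell_population(list(clone(kt, 1)))
  pr <- u937_fish_probes()
  for (nm in c("RP11-500O11", "RP11-717H21", "D20S108", "FLI1", "MYH11")) {
    p <- pr[pr$name == nm, ]
    res <- simulate_locus_fish(p, kt, map)
    expect_equal(sum(res$copies),
                 round(copy_number_profile(pop1, p$chrom, p$start, p$end)),
                 info = nm)
  }
})

test_that("interphase FISH is binomial, seeded, and unbiased", {
  pop <- fixture_pop()
  pr <- u937_fish_probes()
  p <- pr[pr$name == "RP11-317O24", ]
  r <- simulate_interphase_fish(p, pop, 100, seed = 7,
                                member = "der(5)t(5;13)")
  expect_equal(r$true_fraction, 0.7)
  expect_equal(r$n_present + r$n_absent, 100)
  r2 <- simulate_interphase_fish(p, pop, 100, seed = 7,
                                 member = "der(5)t(5;13)")
  expect_identical(r, r2)
  # always-present probe
  r3 <- simulate_interphase_fish(p, pop, 50, seed = 1)  # anywhere in cell
  expect_equal(r3$n_present, 50)
  # unbiased across seeds: mean presence within 3 binomial SEs of truth
  n_cells <- 40
  hits <- vapply(1:400, function(s) {
    simulate_interphase_fish(p, pop, n_cells, seed = s,
                             member = "der(5)t(5;13)")$n_present
  }, 0)
  se <- sqrt(0.7 * 0.3 / (n_cells * 400))
  expect_lt(abs(mean(hits) / n_cells - 0.7), 3 * se)
})
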