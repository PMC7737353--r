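test_that("segment copies distribute across derivatives by FISH evidence", {
  map <- fixture_map()
  kt <- fixture_stemline()
  pr <- u937_fish_probes()
  # two called segments on chromosome 20: the amplified p11.21 region and
  # the retained q11.21 region shared by both abnormal chromosomes
  calls_tab <- data.frame(
    chrom = "20",
    start = c(22400000, 31600000), end = c(22470000, 31880000),
    n_probes = c(30, 30), mean_lrr = NA, bands = NA,
    cn_total = c(6, 4), n_major = NA, n_minor = NA, mosaic_f = NA,
    ambiguous = FALSE, stringsAsFactors = FALSE)
  locus <- do.call(rbind, lapply(c("RP11-500O11", "RP11-702M08",
                                   "RP11-243J16"), function(nm) {
    p <- pr[pr$name == nm, ]
    res <- simulate_locus_fish(p, kt, map)
    i <- if (nm == "RP11-500O11") 1 else 2
    data.frame(chrom = "20", start = calls_tab$start[i],
               end = calls_tab$end[i], member = res$member,
               copies = res$copies, stringsAsFactors = FALSE)
  }))
  cenres <- simulate_centromere_fish("20", kt, map)
  evidence <- list(locus = locus,
                   centromere = data.frame(chrom = "20",
                                           member = cenres$member,
                                           copies = cenres$copies,
                                           active = cenres$active))
  cs <- compose_derivatives(calls_tab, evidence, map)
  d20 <- cs$compositions[["der(20)t(15;20)"]]$content
  expect_equal(d20$copies[d20$start == 22400000], 4)
  d11 <- cs$compositions[["der(11)t(11;16;20)"]]$content
  expect_false(22400000 %in% d11$start)        # amplicon absent from der(11)
  # retained 20q11.21 split: one copy on each abnormal chromosome, the two
  # normal 20s accounting for the rest
  expect_equal(d11$copies[d11$start == 31600000], 1)
  expect_equal(d20$copies[d20$start == 31600000], 1)
  expect_null(cs$conflicts)

  # copy conservation: placed + unplaced equals the called totals
  unplaced_at <- function(cs, start) {
    if (is.null(cs$unplaced)) 0 else
      sum(cs$unplaced$copies[cs$unplaced$start == start])
  }
  for (i in seq_len(nrow(calls_tab))) {
    placed <- sum(vapply(cs$compositions, function(cp) {
      sum(cp$content$copies[cp$content$start == calls_tab$start[i]])
    }, 0))
    expect_equal(placed + unplaced_at(cs, calls_tab$start[i]),
                 calls_tab$cn_total[i])
  }

  # FISH exceeding the called total is a conflict report, not an error
  calls_tab2 <- calls_tab
  calls_tab2$cn_total[1] <- 2
  cs2 <- compose_derivatives(calls_tab2, evidence, map)
  expect_equal(nrow(cs2$conflicts), 1)

  # a segment with no FISH evidence is fully unplaced
  calls_tab3 <- calls_tab[1, ]
  calls_tab3$chrom <- "6"; calls_tab3$start <- 1e6; calls_tab3$end <- 2e6
  cs3 <- compose_derivatives(calls_tab3, evidence, map)
  expect_equal(cs3$unplaced$copies, 6)
})

test_that("the fixture flags exactly one centromere and one telomere capture", {
  map <- fixture_map()
  pop <- fixture_pop()
  cen_calls <- list()
  tel_calls <- list()
  for (cl in pop$clones) {
    for (m in cl$karyotype$members) {
      comp <- as_composition(m, map)
      cc <- detect_centromere_capture(comp, map)
      tc <- detect_telomere_capture(comp, map)
      if (nrow(cc)) cen_calls[[length(cen_calls) + 1]] <- cc
      if (nrow(tc)) tel_calls[[length(tel_calls) + 1]] <- tc
    }
  }
  cen <- unique(do.call(rbind, cen_calls))
  tel <- unique(do.call(rbind, tel_calls))
  expect_equal(cen$derivative, "der(11)t(11;16;20)")
  expect_equal(cen$donor, "11")
  expect_equal(cen$donor_length / 1e6, 6)
  expect_equal(tel$derivative, "der(7)t(6;7)")
  expect_equal(tel$donor, "6")
})

test_that("capture detectors spare donors that are also majority content", {
  map <- fixture_map()
  set.seed(11)
  for (i in 1:20) {
    chs <- sample(map$chrom[1:22], 2)
    kt <- toy_karyotype(map, chs)
    cen1 <- centromere(map, chs[1]); cen2 <- centromere(map, chs[2])
    arm <- sample(c("p", "q"), 1)
    # acrocentric-like short arms cannot host a deep p-arm breakpoint
    if (min(cen1$cen_start, cen2$cen_start) < 25e6) arm <- "q"
    p1 <- if (arm == "p") runif(1, 11e6, cen1$cen_start - 3e6) else
      runif(1, cen1$cen_end + 3e6, chrom_length(map, chs[1]) - 11e6)
    p2 <- if (arm == "p") runif(1, 11e6, cen2$cen_start - 3e6) else
      runif(1, cen2$cen_end + 3e6, chrom_length(map, chs[2]) - 11e6)
    kt2 <- apply_event(kt, rearrangement_event(
      "balanced_translocation", member = paste0(chs[1], ".a1"),
      chrom = chs[1], pos = round(p1), side = arm,
      member2 = paste0(chs[2], ".a1"), chrom2 = chs[2], pos2 = round(p2),
      side2 = arm, new_name = "derA", new_name2 = "derB"), map)
    for (nm in c("derA", "derB")) {
      comp <- as_composition(kt2$members[[nm]], map)
      expect_equal(nrow(detect_centromere_capture(comp, map)), 0, info = nm)
      expect_equal(nrow(detect_telomere_capture(comp, map)), 0, info = nm)
    }
  }
  expect_error(detect_centromere_capture(
    structure(list(content = NULL), class = "derivative_composition"), map),
    "empty")
})

test_that("a constructed shattered-and-rescued chromosome is detected", {
  map <- fixture_map()
  # five acentric fragments of chromosome 4 joined to a 5 Mb pericentric
  # fragment of chromosome 9
  frags <- segment_table(
    chrom = c("4", "4", "4", "4", "9", "4"),
    start = c(1, 20e6, 60e6, 100e6, 41e6, 170e6),
    end = c(12e6, 30e6, 70e6, 110e6, 46e6, 190214555),
    hom = "a")
  der <- derivative("shattered", frags)
  comp <- as_composition(der, map)
  cc <- detect_centromere_capture(comp, map)
  expect_equal(cc$donor, "9")
  expect_equal(cc$kind, "centromere")
})

test_that("homologue assignment separates the two chromosome 16 derivatives", {
  map <- fixture_map()
  kt <- fixture_stemline()
  comps <- lapply(c("16.b1", "der(16)t(4;16)", "der(11)t(11;16;20)"),
                  function(nm) as_composition(kt$members[[nm]], map))
  # truth-derived per-interval (n_major, n_minor) calls for chromosome 16
  calls_tab <- data.frame(
    chrom = "16",
    start = c(1, 22000001, 34000001),
    end = c(22000000, 34000000, 90338345),
    n_major = c(2, 2, 1), n_minor = c(0, 1, 1), stringsAsFactors = FALSE)
  sol <- solve_homologue_assignment("16", calls_tab, comps)
  expect_equal(sol$status, "unique")
  lab <- sol$pieces$label
  names(lab) <- sol$pieces$derivative
  expect_equal(lab[["16.b1"]], lab[["der(11)t(11;16;20)"]])
  expect_false(lab[["16.b1"]] == lab[["der(16)t(4;16)"]])

  verdict <- classify_rearrangement_homologues(
    comps[[2]], comps[[3]], "16", calls_tab,
    other_compositions = comps[1])
  expect_equal(verdict, "different")
  expect_equal(classify_rearrangement_homologues(
    comps[[2]], comps[[2]], "16", calls_tab), "same")
  expect_error(classify_rearrangement_homologues(
    comps[[2]], comps[[3]], "5", calls_tab), "absent")
})

test_that("disjoint single rearrangements cannot be phased to homologues", {
  map <- fixture_map()
  # two derivatives carrying disjoint pieces of chromosome 18: each piece's
  # homologue is unconstrained by dosage, so the relation is ambiguous
  members <- list(normal_chromosome(map, "18", "a", "a1", name = "18.a1"),
                  normal_chromosome(map, "18", "b", "b1", name = "18.b1"),
                  derivative("derA", segment_table("18", 1, 30e6, "a")),
                  derivative("derB", segment_table("18", 50e6, 80373285,
                                                   "b")))
  comps <- lapply(members, function(m) as_composition(m, map))
  calls_tab <- data.frame(chrom = "18",
                          start = c(1, 30e6 + 1, 50e6),
                          end = c(30e6, 50e6 - 1, 80373285),
                          n_major = c(2, 1, 2), n_minor = c(1, 1, 1))
  sol <- solve_homologue_assignment("18", calls_tab, comps)
  expect_equal(sol$status, "ambiguous")
  verdict <- classify_rearrangement_homologues(
    comps[[3]], comps[[4]], "18", calls_tab, other_compositions = comps[1:2])
  expect_equal(verdict, "ambiguous")
})

test_that("random two-derivative scenarios recover homologue truth", {
  map <- fixture_map()
  set.seed(23)
  hits <- 0L
  n_informative <- 0L
  for (i in 1:25) {
    ch <- "12"
    len <- chrom_length(map, ch)
    same <- runif(1) < 0.5
    homs <- if (same) c("a", "a") else c("a", "b")
    # two derivatives each carrying a terminal piece of chromosome 12,
    # plus one intact copy of each homologue
    bp1 <- round(runif(1, 45e6, 90e6))
    bp2 <- round(runif(1, 95e6, 125e6))
    derA <- derivative("derA", segment_table(ch, 1, bp1, homs[1]))
    derB <- derivative("derB", segment_table(ch, 1, bp2, homs[2]))
    members <- list(normal_chromosome(map, ch, "a", "a1", name = "12.a1"),
                    normal_chromosome(map, ch, "b", "b1", name = "12.b1"),
                    derA, derB)
    pop <- cell_population(list(clone(karyotype("kt", members), 1)))
    cuts <- sort(c(bp1, bp2))
    calls_tab <- data.frame(chrom = ch,
                            start = c(1, cuts[1] + 1, cuts[2] + 1),
                            end = c(cuts[1], cuts[2], len))
    dos <- t(vapply(seq_len(nrow(calls_tab)), function(k) {
      homologue_dosage_profile(pop, ch, calls_tab$start[k],
                               calls_tab$end[k])
    }, c(a = 0, b = 0)))
    calls_tab$n_major <- apply(dos, 1, max)
    calls_tab$n_minor <- apply(dos, 1, min)
    comps <- lapply(members, function(m) as_composition(m, map))
    verdict <- classify_rearrangement_homologues(
      comps[[3]], comps[[4]], ch, calls_tab,
      other_compositions = comps[1:2])
    truth <- if (same) "same" else "different"
    if (verdict != "ambiguous") {
      n_informative <- n_informative + 1L
      if (verdict == truth) hits <- hits + 1L
    }
  }
  expect_gt(n_informative, 15)
  expect_equal(hits, n_informative)   # never wrong when dosages differ
})
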