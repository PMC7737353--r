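test_that("rearrangement events conserve base content as expected", {
  map <- fixture_map()
  kt <- toy_karyotype(map)
  bp0 <- total_bp(kt)

  # balanced translocation conserves total bp and swaps distal arms
  ev <- rearrangement_event("balanced_translocation",
                            member = "1.a1", chrom = "1", pos = 88e6,
                            side = "p", member2 = "2.b1", chrom2 = "2",
                            pos2 = 120e6, side2 = "q",
                            new_name = "der(1)", new_name2 = "der(2)")
  kt2 <- apply_event(kt, ev, map)
  expect_equal(total_bp(kt2), bp0)
  expect_setequal(unique(kt2$members[["der(1)"]]$segments$chrom), c("1", "2"))

  # deletion removes exactly the interval length
  del <- rearrangement_event("deletion", member = "1.a1", chrom = "1",
                             start = 10e6, end = 15e6)
  expect_equal(total_bp(kt) - total_bp(apply_event(kt, del, map)), 5e6 + 1)

  # duplication adds it; amplification adds (count-1) copies
  dup <- rearrangement_event("tandem_duplication", member = "1.a1",
                             chrom = "1", start = 10e6, end = 15e6)
  expect_equal(total_bp(apply_event(kt, dup, map)) - bp0, 5e6 + 1)
  amp <- rearrangement_event("amplification", member = "1.a1", chrom = "1",
                             start = 10e6, end = 15e6, count = 5)
  expect_equal(total_bp(apply_event(kt, amp, map)) - bp0, 4 * (5e6 + 1))

  # whole-genome duplication doubles the designated complement and the
  # copies share the founder haplotype, so a post-duplication het probe in a
  # 3-copy region shows bands {1/3, 2/3}, never 1/2
  wgd <- rearrangement_event("whole_genome_duplication",
                             members = c("1.a1", "2.a1"),
                             copy_names = c("1.a2", "2.a2"))
  kt3 <- apply_event(kt, wgd, map)
  expect_equal(count_chromosomes(kt3), 6)
  pop3 <- cell_population(list(clone(kt3, 1)))
  d <- homologue_dosage_profile(pop3, "1", 50e6, 51e6)
  expect_equal(unname(d), c(2, 1))
  expect_equal(baf_band_set(2, 1), c(0, 1 / 3, 2 / 3, 1))

  # coordinate errors are caught
  bad <- rearrangement_event("deletion", member = "1.a1", chrom = "1",
                             start = 1, end = 9e9)
  expect_error(apply_event(kt, bad, map), "coordinate")
  expect_error(apply_event(kt, rearrangement_event(
    "chromosome_loss", member = "nope")), "no member")
})

test_that("viability verdicts follow centromere and telomere evidence", {
  map <- fixture_map()
  norm <- normal_chromosome(map, "7", "a")
  v <- validate_chromosome(norm, map)
  expect_equal(v$verdict, "viable")
  expect_equal(v$n_active_centromeres, 1)
  expect_true(v$telomere_p && v$telomere_q)

  # acentric fragment: distal 16p only
  acent <- derivative("16p-frag", segment_table("16", 1, 20e6, "a"))
  expect_equal(validate_chromosome(acent, map)$verdict, "acentric")

  # terminal deletion without telomere annotation is unterminated
  del <- derivative("del", segment_table("7", 1, 100e6, "a"))
  expect_equal(validate_chromosome(del, map)$verdict, "unterminated")
  del$assume_telomere <- c(FALSE, TRUE)
  expect_equal(validate_chromosome(del, map)$verdict, "viable")

  # pseudodicentric: two centromeres, one inactive, still viable
  psu <- fixture_stemline()$members[["psu dic(3;1)(q25.1;p11.1)"]]
  vp <- validate_chromosome(psu, map)
  expect_equal(vp$verdict, "dicentric-viable")
  expect_equal(vp$n_centromeres, 2)
  expect_equal(vp$n_active_centromeres, 1)
})

test_that("chromosome counting matches the encoded clone structure", {
  pop <- fixture_pop()
  counts <- vapply(pop$clones, function(cl) count_chromosomes(cl$karyotype),
                   0L)
  expect_equal(counts, c(62L, 63L, 60L))
  expect_equal(count_chromosomes(karyotype("empty", list())), 0)
  kt <- apply_event(fixture_stemline(),
                    rearrangement_event("chromosome_gain", member = "8.a1",
                                        new_name = "8+"))
  expect_equal(count_chromosomes(kt), 63)
})

test_that("copy number and homologue dosage profiles match the fixture", {
  pop <- fixture_pop()
  # chromosome 6 state series
  expect_equal(copy_number_profile(pop, "6", 1e6, 25e6), 2)
  expect_equal(copy_number_profile(pop, "6", 27e6, 33e6), 3)
  expect_equal(copy_number_profile(pop, "6", 36.5e6, 47.5e6), 4)
  expect_equal(copy_number_profile(pop, "6", 49e6, 164e6), 3.5)
  expect_equal(unname(homologue_dosage_profile(pop, "6", 49e6, 164e6)),
               c(2, 1.5))
  expect_equal(unname(homologue_dosage_profile(pop, "6", 34.1e6, 35.9e6)),
               c(2, 6))
  # 20q12 common deleted region: two copies of one homologue only
  d20 <- homologue_dosage_profile(pop, "20", 42201817, 42202000)
  expect_equal(sort(unname(d20)), c(0, 2))
  expect_equal(copy_number_profile(pop, "20", 42201817, 42202000), 2)
  # chromosome absent from all clones
  expect_equal(copy_number_profile(pop, "Y", 1e6, 2e6), 0)
  # errors
  expect_error(copy_number_profile(pop, c("1", "2"), 1, 2))
})

test_that("profiles are additive over homologues on random intervals", {
  pop <- fixture_pop()
  map <- fixture_map()
  set.seed(42)
  for (i in 1:25) {
    ch <- sample(map$chrom, 1)
    len <- chrom_length(map, ch)
    s <- runif(1, 1, len - 1e6)
    e <- s + runif(1, 1e5, 5e7)
    e <- min(e, len)
    d <- homologue_dosage_profile(pop, ch, s, e)
    expect_equal(copy_number_profile(pop, ch, s, e), unname(d[1] + d[2]))
  }
})

test_that("the fixture event history reproduces key members segment-for-segment", {
  kt <- fixture_stemline()
  der11 <- kt$members[["der(11)t(11;16;20)"]]$segments
  expect_equal(der11$chrom, c("16", "11", "11", "20", "20"))
  expect_equal(der11$start, c(1, 49000001, 127250001, 31590001, 1))
  expect_equal(der11$end, c(34e6, 55e6, 129150000, 32e6, 8e6))
  expect_equal(der11$end[2] - der11$start[2] + 1, 6e6)

  der10 <- kt$members[["der(10)t(10;11)dup(10)"]]$segments
  expect_equal(der10$chrom, c("11", "10", "10"))
  expect_equal(der10$strand[1], "-")      # 11qter cap reads inverted
  expect_equal(der10$hom, c("b", "b", "a"))  # distal 10q converted

  # the der(20) carries the 20p11.21 amplicon with one inverted repeat
  der20 <- kt$members[["der(20)t(15;20)"]]$segments
  amp <- der20[der20$chrom == "20" & der20$start >= 22e6 &
                 der20$end <= 24e6, ]
  expect_equal(sum(amp$strand == "-"), 1)
  expect_equal(nrow(amp), 3)
})
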