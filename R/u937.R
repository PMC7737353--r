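#' @name u937
#' @title Encoded U937 cell-line fixture
#'
#' @description
#' A three-clone model of the near-triploid U937 myeloid cell line,
#' constructed as an explicit rearrangement-event history applied to a
#' triploid founder (whole-genome duplication of one designated haploid
#' complement, homologue "a" of every autosome plus the X). Breakpoints are
#' placed at GRCh38-scale coordinates consistent with the published band
#' assignments and targeted-FISH probe positions; they are approximations at
#' band resolution, chosen once, and the inference and assembly code treats
#' them as unknowns.
#'
#' Salient encoded facts: stemline of 62 chromosomes; two normal copies of one
#' chromosome 20 homologue and complex rearrangement of the other with loss of
#' the 20q12 common deleted region (LOH with copy number 2); a
#' der(11)t(11;16;20) whose only centromere sits on a 6 Mb captured
#' chromosome-11 pericentromeric fragment; a der(20)t(15;20) with a duplicated
#' and amplified 20p11.21 subsection (up to 4 copy-equivalents, one inverted
#' repeat); a 50%-mosaic der(6)del(6)dup(6) carrying 10 copies of a 6p21.3
#' amplicon; a der(5)t(5;13) with two overlapping 5q11.2 deletions, the larger
#' present in 30% of cells; a mosaic der(7)t(6;7) capped by a 6q subtelomeric
#' segment.
NULL

# -- fixture coordinates (bp, GRCh38 scale) ---------------------------------

u937_coords <- function() {
  list(
    # chromosome 11 pericentromeric captured fragment: exactly 6 Mb
    chr11_pericen = c(49000001, 55000000),
    # 11q24.2->11q24.3 fragment on the der(11)t(11;16;20)
    chr11_q24 = c(127250001, 129150000),
    # printed boundary uncertainty intervals for the 11q24 fragment
    chr11_q24_bounds = list(proximal = c(127168221, 127348488),
                            distal = c(129066363, 129199648)),
    # der(11) chromosome-20 content
    der11_20q11 = c(31590001, 32000000),
    der11_20p = c(1, 8000000),
    # der(20) blocks
    der20_20p = c(1, 11900000),
    der20_20q_bp = 33400000,
    der20_mid_del = c(11900001, 21999999),
    der20_15q = c(34500000, 85500000),
    der20_15q_del1 = c(37300000, 51390000),
    der20_15q_dup1 = c(51400000, 56000000),
    der20_15q_del2 = c(60100000, 60600000),
    der20_15q_dup2 = c(80900000, 82000000),
    der20_amp1 = c(22350000, 23700000),
    der20_amp2 = c(22350000, 23000000),
    der20_amp3 = c(22350000, 22500000),
    # chromosome 5 proximal-q deletions on the der(5)t(5;13)
    chr5_small_del = c(51500000, 56500000),
    chr5_large_del = c(50280000, 58000000),
    # chromosome 6 state boundaries
    chr6_t26_bp = 26000000,     # der(6)t(2;6) breakpoint (6p22.1)
    chr6_amp = c(34000001, 36000000),   # 6p21.3 amplicon, x10 on the der
    chr6_dup = c(36000001, 48000000),   # 6p21.31->6p12.x duplication
    chr6_qter = c(165000001, 170805979) # 6q26->qter capture on der(7)
  )
}

u937_founder <- function(map) {
  members <- list()
  for (ch in c(as.character(1:22), "X", "Y")) {
    if (ch != "Y") {
      members <- c(members, list(
        normal_chromosome(map, ch, "a", "a1", name = paste0(ch, ".a1"))))
    }
    if (ch != "X") {
      members <- c(members, list(
        normal_chromosome(map, ch, "b", "b1", name = paste0(ch, ".b1"))))
    }
  }
  karyotype("founder", members)
}

u937_common_events <- function() {
  co <- u937_coords()
  ev <- function(...) rearrangement_event(...)
  list(
    # triploidisation: duplicate the "a" complement (plus X), then lose the Y
    ev("whole_genome_duplication",
       members = c(paste0(1:22, ".a1"), "X.a1"),
       copy_names = c(paste0(1:22, ".a2"), "X.a2")),
    ev("chromosome_loss", member = "Y.b1"),

    # chromosome 1
    ev("deletion", member = "1.b1", chrom = "1",
       start = 130000000, end = 248956422, new_name = "del(1)(q12)"),
    ev("unbalanced_translocation", member = "1.a2", chrom = "1",
       pos = 88000000, side = "p",
       member2 = "5.b1", chrom2 = "5", pos2 = 135000000, side2 = "q",
       new_name = "der(1)t(1;5)"),

    # chromosome 2
    ev("deletion", member = "2.b1", chrom = "2", start = 1, end = 87000000,
       new_name = "del(2)(p11.2)"),
    ev("tandem_duplication", member = "2.a2", chrom = "2",
       start = 159000000, end = 198000000),
    ev("deletion", member = "2.a2", chrom = "2",
       start = 198000001, end = 242193529, new_name = "der(2)dup(2)del(2)"),

    # chromosome 3 (+ captured 1q making the psu dic)
    ev("deletion", member = "3.a2", chrom = "3",
       start = 113000000, end = 146000000, new_name = "del(3)(q13.33q24)"),
    ev("deletion", member = "3.b1", chrom = "3",
       start = 152000001, end = 198295559),
    ev("segment_capture", member = "3.b1", side = "q",
       member2 = "1.a1", chrom2 = "1", start2 = 120700001, end2 = 248956422,
       orientation = "+", piece_cen_active = FALSE,
       new_name = "psu dic(3;1)(q25.1;p11.1)"),

    # chromosomes 4 and 16
    ev("unbalanced_translocation", member = "16.a2", chrom = "16",
       pos = 22000000, side = "p",
       member2 = "4.b1", chrom2 = "4", pos2 = 44000000, side2 = "p",
       new_name = "der(16)t(4;16)"),
    ev("chromosome_loss", member = "4.b1"),
    ev("deletion", member = "der(16)t(4;16)", chrom = "4",
       start = 38000000, end = 38600000),
    ev("deletion", member = "der(16)t(4;16)", chrom = "4",
       start = 30000000, end = 30500000),
    ev("deletion", member = "der(16)t(4;16)", chrom = "4",
       start = 10000000, end = 12000000),
    ev("chromosome_loss", member = "16.a1"),

    # chromosome 5 (5.b1 was truncated by the t(1;5) above)
    ev("unbalanced_translocation", member = "5.b1", chrom = "5",
       pos = 59000000, side = "q",
       member2 = "13.b1", chrom2 = "13", pos2 = 41000000, side2 = "q",
       new_name = "der(5)t(5;13)"),
    ev("chromosome_loss", member = "13.b1"),
    ev("deletion", member = "der(5)t(5;13)", chrom = "5",
       start = co$chr5_small_del[1], end = co$chr5_small_del[2]),
    ev("unbalanced_translocation", member = "5.a2", chrom = "5",
       pos = 128000000, side = "q",
       member2 = "1.a1", chrom2 = "1", pos2 = 88000000, side2 = "p",
       duplicative = TRUE, new_name = "der(5)t(1;5)"),

    # chromosome 6 (stemline part)
    ev("unbalanced_translocation", member = "6.a2", chrom = "6",
       pos = co$chr6_t26_bp, side = "p",
       member2 = "2.a1", chrom2 = "2", pos2 = 72000000, side2 = "p",
       duplicative = TRUE, new_name = "der(6)t(2;6)"),

    # chromosome 7: fourth copy with a 7p15 duplication
    ev("chromosome_gain", member = "7.b1", founder_suffix = "2",
       new_name = "7.b2"),
    ev("tandem_duplication", member = "7.b2", chrom = "7",
       start = 21000000, end = 28500000, new_name = "dup(7)(p15.3p15.1)"),

    # chromosome 8: subtelomeric 8p duplication on an apparently normal 8
    ev("tandem_duplication", member = "8.a1", chrom = "8",
       start = 1, end = 700000),

    # chromosomes 10 and 11: the balanced t(10;11) (pre-duplication
    # homologues) and the der(10) intra-10 duplication/conversion
    ev("balanced_translocation", member = "10.b1", chrom = "10",
       pos = 25000000, side = "p",
       member2 = "11.b1", chrom2 = "11", pos2 = 87000000, side2 = "q",
       new_name = "der(10)t(10;11)", new_name2 = "der(11)t(10;11)"),
    ev("unbalanced_translocation", member = "der(10)t(10;11)", chrom = "10",
       pos = 113500000, side = "q",
       member2 = "10.a2", chrom2 = "10", pos2 = 96000000, side2 = "q",
       duplicative = TRUE, new_name = "der(10)t(10;11)dup(10)"),
    ev("chromosome_loss", member = "10.a2"),

    # der(11)t(11;16;20): pericentromeric 11 fragment + 11q24 fragment,
    # 16p attached at the p end, 20q11.21 fragment and 20p tip at the q end
    ev("deletion", member = "11.a2", chrom = "11",
       start = 1, end = co$chr11_pericen[1] - 1),
    ev("deletion", member = "11.a2", chrom = "11",
       start = co$chr11_pericen[2] + 1, end = co$chr11_q24[1] - 1),
    ev("deletion", member = "11.a2", chrom = "11",
       start = co$chr11_q24[2] + 1, end = 135086622),
    ev("segment_capture", member = "11.a2", side = "p",
       member2 = "16.b1", chrom2 = "16", start2 = 1, end2 = 34000000,
       orientation = "+"),
    ev("segment_capture", member = "11.a2", side = "q",
       member2 = "20.b1", chrom2 = "20",
       start2 = co$der11_20q11[1], end2 = co$der11_20q11[2],
       orientation = "+"),
    ev("segment_capture", member = "11.a2", side = "q",
       member2 = "20.b1", chrom2 = "20",
       start2 = co$der11_20p[1], end2 = co$der11_20p[2],
       orientation = "-", new_name = "der(11)t(11;16;20)"),

    # chromosomes reverted to two copies after triploidisation
    ev("chromosome_loss", member = "9.a2"),
    ev("chromosome_loss", member = "14.a2"),
    ev("chromosome_loss", member = "17.a2"),

    # chromosome 17: short-arm homologue replacement (LOH over 17p)
    ev("deletion", member = "17.b1", chrom = "17", start = 1, end = 20000000),
    ev("segment_capture", member = "17.b1", side = "p",
       member2 = "17.a1", chrom2 = "17", start2 = 1, end2 = 20000000,
       orientation = "+"),

    # der(20)t(15;20)
    ev("deletion", member = "20.b1", chrom = "20",
       start = co$der20_20q_bp + 1, end = 64444167),
    ev("deletion", member = "20.b1", chrom = "20",
       start = co$der20_mid_del[1], end = co$der20_mid_del[2]),
    ev("segment_capture", member = "20.b1", after = 1,
       member2 = "15.a2", chrom2 = "15",
       start2 = co$der20_15q[1], end2 = co$der20_15q[2], orientation = "+"),
    ev("deletion", member = "20.b1", chrom = "15",
       start = co$der20_15q_del1[1], end = co$der20_15q_del1[2]),
    ev("tandem_duplication", member = "20.b1", chrom = "15",
       start = co$der20_15q_dup1[1], end = co$der20_15q_dup1[2]),
    ev("deletion", member = "20.b1", chrom = "15",
       start = co$der20_15q_del2[1], end = co$der20_15q_del2[2]),
    ev("tandem_duplication", member = "20.b1", chrom = "15",
       start = co$der20_15q_dup2[1], end = co$der20_15q_dup2[2]),
    ev("segment_capture", member = "20.b1", side = "q",
       member2 = "20.b1", chrom2 = "20",
       start2 = co$der20_amp1[1], end2 = co$der20_amp1[2], orientation = "+"),
    ev("segment_capture", member = "20.b1", side = "q",
       member2 = "20.b1", chrom2 = "20",
       start2 = co$der20_amp2[1], end2 = co$der20_amp2[2], orientation = "-"),
    ev("segment_capture", member = "20.b1", side = "q",
       member2 = "20.b1", chrom2 = "20",
       start2 = co$der20_amp3[1], end2 = co$der20_amp3[2], orientation = "+",
       new_name = "der(20)t(15;20)")
  )
}

u937_clone2_events <- function() {
  co <- u937_coords()
  ev <- function(...) rearrangement_event(...)
  list(
    ev("chromosome_gain", member = "6.b1", founder_suffix = "2",
       new_name = "6.b2"),
    ev("deletion", member = "6.b2", chrom = "6",
       start = 1, end = co$chr6_amp[1] - 1),
    ev("amplification", member = "6.b2", chrom = "6",
       start = co$chr6_amp[1], end = co$chr6_amp[2], count = 10),
    ev("tandem_duplication", member = "6.b2", chrom = "6",
       start = co$chr6_dup[1], end = co$chr6_dup[2],
       new_name = "der(6)del(6)dup(6)"),
    ev("deletion", member = "7.a2", chrom = "7",
       start = 100000000, end = 142000000, new_name = "del(7)(q22.1q34)")
  )
}

u937_clone3_events <- function() {
  co <- u937_coords()
  ev <- function(...) rearrangement_event(...)
  list(
    ev("deletion", member = "7.a2", chrom = "7",
       start = 86400001, end = 159345973),
    ev("segment_capture", member = "7.a2", side = "q",
       member2 = "6.a1", chrom2 = "6",
       start2 = co$chr6_qter[1], end2 = co$chr6_qter[2],
       orientation = "+", new_name = "der(7)t(6;7)"),
    ev("chromosome_loss", member = "12.a2"),
    ev("chromosome_loss", member = "22.a2")
  )
}

u937_set_telomere_assumptions <- function(kt) {
  assume <- list("del(1)(q12)" = c(FALSE, TRUE),
                 "del(2)(p11.2)" = c(TRUE, FALSE),
                 "der(2)dup(2)del(2)" = c(FALSE, TRUE),
                 "der(6)del(6)dup(6)" = c(TRUE, FALSE),
                 "der(20)t(15;20)" = c(FALSE, TRUE))
  for (nm in names(assume)) {
    if (!is.null(kt$members[[nm]])) {
      kt$members[[nm]]$assume_telomere <- assume[[nm]]
    }
  }
  kt
}

#' Construct the U937 cell population fixture
#'
#' Three clones plus one cross-cutting sub-mosaic event (the larger 5q11.2
#' deletion of the der(5)t(5;13), present in 30% of cells, clone membership
#' unresolved).
#'
#' @param mode `"nominal"` uses rounded clone fractions 0.30 / 0.50 / 0.20
#'   (the der(6)del(6)dup(6)-bearing clone at 50%); `"counts"` uses the
#'   karyotyped cell counts 21/71, 37/71, 13/71.
#' @param map A [genome_map()] (the default built-in map).
#' @return A [cell_population()] with three clones; the stemline has 62
#'   chromosomes, the der(6)-bearing clone 63, the der(7)t(6;7)-bearing
#'   clone 60.
#' @export
u937_fixture <- function(mode = c("nominal", "counts"), map = genome_map()) {
  mode <- match.arg(mode)
  base <- apply_events(u937_founder(map), u937_common_events(), map)
  base <- u937_set_telomere_assumptions(base)
  kt1 <- base
  kt1$name <- "U937 stemline"
  kt2 <- apply_events(base, u937_clone2_events(), map)
  kt2$name <- "U937 clone 2 (+der(6)del(6)dup(6), del(7q))"
  kt3 <- apply_events(base, u937_clone3_events(), map)
  kt3$name <- "U937 clone 3 (der(7)t(6;7), -12, -22)"
  fr <- if (mode == "nominal") c(0.30, 0.50, 0.20) else c(21, 37, 13) / 71
  co <- u937_coords()
  cell_population(
    clones = list(clone(kt1, fr[1]), clone(kt2, fr[2]), clone(kt3, fr[3])),
    submosaics = list(list(
      member = "der(5)t(5;13)",
      event = rearrangement_event("deletion", member = "der(5)t(5;13)",
                                  chrom = "5", start = co$chr5_large_del[1],
                                  end = co$chr5_large_del[2]),
      fraction = 0.30)))
}

#' Minimum guaranteed span between two uncertain breakpoint boundaries
#'
#' For a segment whose proximal breakpoint lies somewhere inside one printed
#' interval and whose distal breakpoint lies inside another, the minimum
#' length the segment can have is the distance from the proximal interval's
#' high end to the distal interval's low end.
#'
#' @param proximal,distal Length-2 numeric vectors `c(low, high)` of the two
#'   printed boundary-uncertainty intervals (bp).
#' @return Minimum segment length in bp.
#' @export
min_segment_span <- function(proximal, distal) {
  unname(distal[1] - proximal[2] + 1)
}

#' Printed boundary intervals of the der(11)t(11;16;20) 11q24 fragment
#' @return List with `proximal` and `distal` `c(low, high)` bp intervals.
#' @export
u937_11q24_bounds <- function() u937_coords()$chr11_q24_bounds
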