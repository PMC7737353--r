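#' Average copy number of an interval across a cell population
#'
#' Clone fractions (and cross-cutting sub-mosaic events) weight each clone's
#' integer copy count; partially overlapping segments count proportionally to
#' their overlap with the query interval.
#'
#' @param pop A [cell_population()].
#' @param chrom Chromosome of the query interval.
#' @param start,end Query interval (1-based inclusive, single chromosome).
#' @return Average copy number (float).
#' @export
copy_number_profile <- function(pop, chrom, start, end) {
  d <- homologue_dosage_profile(pop, chrom, start, end)
  unname(d[1] + d[2])
}

#' Average per-homologue dosage of an interval across a cell population
#'
#' @inheritParams copy_number_profile
#' @return Named numeric vector `c(a = , b = )` of average copies of each
#'   homologue (labels are the two homologue tags of the chromosome).
#' @export
homologue_dosage_profile <- function(pop, chrom, start, end) {
  stopifnot(length(chrom) == 1, end >= start)
  chrom <- as.character(chrom)
  width <- end - start + 1
  acc <- c(a = 0, b = 0)
  for (e in effective_clones(pop)) {
    for (m in e$karyotype$members) {
      seg <- m$segments
      sel <- seg$chrom == chrom
      if (!any(sel)) next
      ov <- interval_overlap(seg$start[sel], seg$end[sel], start, end) / width
      for (h in c("a", "b")) {
        hs <- seg$hom[sel] == h
        if (any(hs)) acc[h] <- acc[h] + e$fraction * sum(ov[hs])
      }
    }
  }
  acc
}

# per-clone integer homologue dosage at point positions (vectorised over pos);
# returns a list(a = counts, b = counts)
point_dosage <- function(kt, chrom, pos) {
  a <- numeric(length(pos))
  b <- numeric(length(pos))
  for (m in kt$members) {
    seg <- m$segments
    sel <- which(seg$chrom == chrom)
    for (i in sel) {
      hit <- pos >= seg$start[i] & pos <= seg$end[i]
      if (seg$hom[i] == "a") a[hit] <- a[hit] + 1 else b[hit] <- b[hit] + 1
    }
  }
  list(a = a, b = b)
}

#' Maximum per-member copy count of an interval
#'
#' For each member of a karyotype, the number of segment copies fully
#' containing the query interval; useful for questions like "what is the
#' highest copy count of this material on any single abnormal chromosome".
#'
#' @param kt A [karyotype()].
#' @param chrom,start,end Query interval.
#' @return Named integer vector, one entry per member.
#' @export
member_copy_counts <- function(kt, chrom, start, end) {
  vapply(kt$members, function(m) {
    seg <- m$segments
    sum(seg$chrom == chrom & seg$start <= start & seg$end >= end)
  }, 0L)
}
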