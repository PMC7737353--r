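#' Build a segment table for a derivative chromosome
#'
#' Segments are the ordered building blocks of a (derivative) chromosome:
#' intervals of a source chromosome carrying a homologue tag, a founder-copy
#' identifier (which post-duplication physical copy of that homologue the
#' material descends from; copies created by whole-genome duplication share
#' the same haplotype), an orientation, and a centromere-activity flag that is
#' meaningful only where the segment overlaps its source centromere.
#'
#' @param chrom Source chromosome name per segment.
#' @param start,end 1-based inclusive interval on the source chromosome.
#' @param hom Homologue tag, one of the two labels per chromosome
#'   (conventionally `"a"` and `"b"`).
#' @param founder Founder-copy identifier, e.g. `"a1"`, `"a2"`, `"b1"`.
#'   The leading letter must match `hom`; the haplotype (genotype source) of a
#'   founder copy is its homologue tag.
#' @param strand `"+"` (forward, pter-to-qter reading) or `"-"` (inverted).
#' @param cen_active Logical; whether a centromere contained in the segment is
#'   active. Ignored for segments not overlapping a centromere.
#' @return A `data.frame` with one row per segment.
#' @export
segment_table <- function(chrom, start, end, hom, founder = paste0(hom, "1"),
                          strand = "+", cen_active = TRUE) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), hom = as.character(hom),
                   founder = as.character(founder),
                   strand = as.character(strand),
                   cen_active = as.logical(cen_active),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$start >= 1), all(df$end >= df$start),
            all(df$strand %in% c("+", "-")))
  df
}

#' Construct a derivative chromosome
#'
#' Normal chromosomes are single-segment derivatives. Segment order is the
#' physical order from the p-terminal end to the q-terminal end.
#'
#' @param name Chromosome name (ISCN-flavoured free text, e.g.
#'   `"der(11)t(11;16;20)"` or `"7"`).
#' @param segments A segment table from [segment_table()].
#' @param assume_telomere Length-2 logical `(p, q)`: treat the corresponding
#'   end as capped by a telomere even when no subtelomeric array segment
#'   reaches it (telomere healing or capping invisible to the array).
#' @return An object of class `derivative`.
#' @export
derivative <- function(name, segments, assume_telomere = c(FALSE, FALSE)) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1,
            length(assume_telomere) == 2)
  structure(list(name = name, segments = segments,
                 assume_telomere = as.logical(assume_telomere)),
            class = "derivative")
}

#' Normal chromosome as a single-segment derivative
#' @param map A [genome_map()].
#' @param chrom Chromosome name.
#' @param hom Homologue tag.
#' @param founder Founder-copy identifier.
#' @param name Optional member name; defaults to the chromosome name.
#' @export
normal_chromosome <- function(map, chrom, hom, founder = paste0(hom, "1"),
                              name = as.character(chrom)) {
  derivative(name, segment_table(chrom, 1, chrom_length(map, chrom), hom,
                                 founder))
}

#' @export
print.derivative <- function(x, ...) {
  cat("<derivative>", x$name, "with", nrow(x$segments), "segment(s)\n")
  invisible(x)
}

#' Construct a karyotype
#'
#' @param name Karyotype (clone) name.
#' @param members List of [derivative()] objects; list names are made unique
#'   automatically from the member names.
#' @return An object of class `karyotype`.
#' @export
karyotype <- function(name, members) {
  stopifnot(all(vapply(members, inherits, TRUE, "derivative")))
  names(members) <- make.unique(vapply(members, `[[`, "", "name"), sep = "#")
  structure(list(name = name, members = members), class = "karyotype")
}

#' Number of chromosomes in a karyotype
#' @param kt A [karyotype()].
#' @return Integer count of members.
#' @export
count_chromosomes <- function(kt) length(kt$members)

#' @export
print.karyotype <- function(x, ...) {
  cat("<karyotype>", x$name, "-", count_chromosomes(x), "chromosomes\n")
  invisible(x)
}

#' Construct a clone (karyotype with a cell fraction)
#' @param kt A [karyotype()].
#' @param fraction Cell fraction in \[0, 1\].
#' @export
clone <- function(kt, fraction) {
  stopifnot(inherits(kt, "karyotype"), fraction >= 0, fraction <= 1)
  structure(list(karyotype = kt, fraction = fraction), class = "clone")
}

#' Construct a cell population
#'
#' A mixture of clones, optionally with cross-cutting sub-mosaic events: a
#' rearrangement present in a stated fraction of cells independently of the
#' clone structure (used when the data do not resolve which clone carries an
#' event).
#'
#' @param clones List of [clone()] objects; fractions must sum to 1.
#' @param submosaics List of entries `list(member =, event =, fraction =)`:
#'   in `fraction` of cells (independently of clone), `event` (a
#'   [rearrangement_event()]) is applied to the member named `member`.
#' @export
cell_population <- function(clones, submosaics = list()) {
  stopifnot(all(vapply(clones, inherits, TRUE, "clone")))
  fr <- vapply(clones, `[[`, 0, "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("clone fractions must sum to 1")
  for (sm in submosaics) {
    stopifnot(is.character(sm$member), sm$fraction >= 0, sm$fraction <= 1)
  }
  structure(list(clones = clones, submosaics = submosaics),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population>", length(x$clones), "clone(s);",
      length(x$submosaics), "sub-mosaic event(s)\n")
  for (cl in x$clones) {
    cat(sprintf("  %-28s fraction %.3f, %d chromosomes\n", cl$karyotype$name,
                cl$fraction, count_chromosomes(cl$karyotype)))
  }
  invisible(x)
}

#' Expand a population into effective clones
#'
#' Cross-cutting sub-mosaic events are combined with the clone structure by
#' taking the product of independent presence/absence states, giving a flat
#' list of `list(karyotype =, fraction =)` entries whose fractions sum to 1.
#'
#' @param pop A [cell_population()].
#' @return List of effective clones.
#' @export
effective_clones <- function(pop) {
  eff <- lapply(pop$clones, function(cl) {
    list(karyotype = cl$karyotype, fraction = cl$fraction)
  })
  for (sm in pop$submosaics) {
    nxt <- list()
    for (e in eff) {
      has <- !is.null(e$karyotype$members[[sm$member]])
      if (has && sm$fraction > 0) {
        kt2 <- apply_event(e$karyotype, sm$event)
        nxt <- c(nxt, list(list(karyotype = kt2,
                                fraction = e$fraction * sm$fraction)))
      }
      keep <- if (has) e$fraction * (1 - sm$fraction) else e$fraction
      if (keep > 0) {
        nxt <- c(nxt, list(list(karyotype = e$karyotype, fraction = keep)))
      }
    }
    eff <- nxt
  }
  eff[vapply(eff, function(e) e$fraction > 0, TRUE)]
}

#' Total base content of a karyotype
#' @param kt A [karyotype()].
#' @return Total bp summed over all member segments.
#' @export
total_bp <- function(kt) {
  sum(vapply(kt$members, function(m) sum(m$segments$end - m$segments$start + 1),
             0))
}
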