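#' Viability check for a (derivative) chromosome
#'
#' A mitotically stable chromosome needs two telomeres and at least one
#' active centromere. Centromeres are counted as segments overlapping the
#' centromere interval of their source chromosome; an end is telomere-bearing
#' when its terminal segment reaches into the subtelomere window of its
#' source chromosome on the outward-facing side (the subtelomere acting as an
#' array-visible proxy for the telomere), or when the derivative carries an
#' explicit `assume_telomere` annotation for that end.
#'
#' Verdicts: `"acentric"` (no active centromere), `"unterminated"` (at least
#' one end without telomere evidence), `"dicentric-viable"` (two or more
#' centromeres, at least one active, both ends capped — pseudodicentrics with
#' one inactivated centromere fall here), `"viable"` otherwise.
#'
#' @param der A [derivative()].
#' @param map A [genome_map()].
#' @return A list of class `viability_report` with fields `n_centromeres`,
#'   `n_active_centromeres`, `telomere_p`, `telomere_q`, `verdict`.
#' @export
validate_chromosome <- function(der, map) {
  seg <- der$segments
  cen <- centromere(map, seg$chrom)
  ov <- interval_overlap(seg$start, seg$end, cen$cen_start, cen$cen_end)
  n_cen <- sum(ov > 0)
  n_act <- sum(ov > 0 & seg$cen_active)

  end_has_telomere <- function(i, outward_p) {
    s <- seg[i, ]
    st <- subtelomeres(map, s$chrom)
    # outward_p: TRUE when this is the first (p-terminal) end of the member.
    # For a forward segment the outward-facing side of the first end is the
    # segment start; inversion swaps the side.
    side_start <- xor(outward_p, s$strand == "-")
    if (side_start) s$start <= st$p[2] else s$end >= st$q[1]
  }
  telo_p <- der$assume_telomere[1] || end_has_telomere(1, TRUE)
  telo_q <- der$assume_telomere[2] || end_has_telomere(nrow(seg), FALSE)

  verdict <- if (n_act == 0) {
    "acentric"
  } else if (!(telo_p && telo_q)) {
    "unterminated"
  } else if (n_cen >= 2) {
    "dicentric-viable"
  } else {
    "viable"
  }
  structure(list(n_centromeres = n_cen, n_active_centromeres = n_act,
                 telomere_p = telo_p, telomere_q = telo_q, verdict = verdict),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  cat(sprintf("<viability> %s (%d centromere(s), %d active; telomeres p=%s q=%s)\n",
              x$verdict, x$n_centromeres, x$n_active_centromeres,
              x$telomere_p, x$telomere_q))
  invisible(x)
}
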