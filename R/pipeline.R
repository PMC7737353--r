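#' Build FISH membership evidence for called segments
#'
#' Simulates one locus probe per called segment (a short interval at the
#' segment midpoint) against a metaphase karyotype, plus centromere probes
#' for every chromosome of the map — the targeted-FISH step that localises
#' array segments on specific chromosomes.
#'
#' @param calls A `segment_calls` object (or its table).
#' @param kt The metaphase [karyotype()] probed.
#' @param map A [genome_map()].
#' @param halfwidth Half-width (bp) of each synthetic locus probe.
#' @return Evidence list (`locus`, `centromere`) for
#'   [compose_derivatives()].
#' @export
fish_evidence_for_calls <- function(calls, kt, map, halfwidth = 25000) {
  tab <- if (inherits(calls, "segment_calls")) calls$table else calls
  locus <- list()
  for (i in seq_len(nrow(tab))) {
    s <- tab[i, ]
    mid <- round((s$start + s$end) / 2)
    pr <- fish_probes(paste0("seg", i), "locus", s$chrom,
                      max(1, mid - halfwidth),
                      min(chrom_length(map, s$chrom), mid + halfwidth))
    res <- simulate_locus_fish(pr, kt, map)
    locus[[i]] <- data.frame(chrom = s$chrom, start = s$start, end = s$end,
                             member = res$member, copies = res$copies,
                             stringsAsFactors = FALSE)
  }
  cen <- list()
  for (ch in map$chrom) {
    res <- simulate_centromere_fish(ch, kt, map)
    cen[[length(cen) + 1]] <- data.frame(chrom = ch, member = res$member,
                                         copies = res$copies,
                                         active = res$active,
                                         stringsAsFactors = FALSE)
  }
  list(locus = do.call(rbind, c(locus, list(make.row.names = FALSE))),
       centromere = do.call(rbind, c(cen, list(make.row.names = FALSE))))
}

#' Run the capture-detection pipeline on a scenario
#'
#' Segments the scenario's array track, calls allele configurations, builds
#' FISH membership evidence against the ancestral clone's metaphases,
#' composes derivative content, and runs the centromere-capture detector on
#' every composition.
#'
#' @param scn A `scenario` from [generate_scenario()].
#' @param ... Passed to [call_segments()].
#' @return List `calls`, `evidence`, `compositions`, `captures` (combined
#'   capture-call data frame across derivatives).
#' @export
detect_scenario_captures <- function(scn, ...) {
  calls <- call_segments(scn$track, ...)
  kt <- scn$pop$clones[[1]]$karyotype
  evidence <- fish_evidence_for_calls(calls, kt, scn$map)
  comps <- compose_derivatives(calls, evidence, scn$map)
  caps <- lapply(comps$compositions, function(comp) {
    if (nrow(comp$content) == 0) return(NULL)
    detect_centromere_capture(comp, scn$map)
  })
  caps <- do.call(rbind, c(caps, list(make.row.names = FALSE)))
  list(calls = calls, evidence = evidence, compositions = comps,
       captures = caps)
}
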