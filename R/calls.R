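#' Segment an array track and call allele configurations
#'
#' The end-to-end per-chromosome inference: changepoint segmentation, BAF
#' band extraction, allele-configuration enumeration, homologue-dosage and
#' mosaic-fraction estimation for every segment with enough informative
#' probes.
#'
#' @param track An `array_track`.
#' @param min_probes Minimum probes per segment (segmentation and calling).
#' @param max_total,max_clones,lambda,step,hom_weight See
#'   [enumerate_configs()].
#' @param penalty Segmentation penalty, see [segment_tracks()].
#' @param min_band_sep Band separation for [extract_baf_bands()].
#' @param mosaic_ci Logical; compute bootstrap CIs for mosaic fractions
#'   (slower).
#' @param seed Seed for the mosaic bootstrap.
#' @return A list of class `segment_calls`: `table` (one row per segment:
#'   `chrom, start, end, n_probes, mean_lrr, bands, cn_total, n_major,
#'   n_minor, mosaic_f, ambiguous`) and `details` (per-segment
#'   `config_ranking`s).
#' @export
call_segments <- function(track, min_probes = 20, max_total = 12,
                          max_clones = 2, lambda = 1, step = 0.01,
                          hom_weight = 0.2, penalty = NULL,
                          min_band_sep = 0.08, mosaic_ci = FALSE, seed = 1) {
  segs <- segment_tracks(track, min_probes = min_probes, penalty = penalty)
  details <- vector("list", nrow(segs))
  rows <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    sel <- track$chrom == s$chrom & track$pos >= s$start &
      track$pos <= s$end
    lrr <- mean(track$lrr[sel])
    n_inf <- sum(sel & !is.na(track$baf))
    row <- data.frame(chrom = s$chrom, start = s$start, end = s$end,
                      n_probes = s$n_probes, mean_lrr = lrr,
                      bands = NA_character_, cn_total = NA_real_,
                      n_major = NA_real_, n_minor = NA_real_,
                      mosaic_f = NA_real_, ambiguous = NA,
                      stringsAsFactors = FALSE)
    if (n_inf >= min(min_probes, 10)) {
      bands <- extract_baf_bands(track, s$chrom, s$start, s$end,
                                 min_sep = min_band_sep)
      rk <- enumerate_configs(bands, lrr, max_total = max_total,
                              max_clones = max_clones, lambda = lambda,
                              step = step, hom_weight = hom_weight)
      cfg <- rk$configs[[1]]
      dos <- infer_homologue_dosage(cfg)
      mosaic_f <- NA_real_
      if (cfg$n_clones == 2) {
        est <- estimate_mosaic_fraction(track, s$chrom, s$start, s$end, cfg,
                                        step = step,
                                        n_boot = if (mosaic_ci) 200 else 0,
                                        seed = seed,
                                        hom_weight = hom_weight)
        # report the fraction of the lower-copy-number state
        totals <- cfg$clones$nA + cfg$clones$nB
        mosaic_f <- if (totals[1] < totals[2]) est$f else 1 - est$f
      }
      row$bands <- paste(sprintf("%.3f:%.2f", bands$center, bands$weight),
                         collapse = ",")
      row$cn_total <- cfg$cn_total
      row$n_major <- unname(dos["n_major"])
      row$n_minor <- unname(dos["n_minor"])
      row$mosaic_f <- mosaic_f
      row$ambiguous <- rk$ambiguous
      details[[i]] <- rk
    }
    rows[[i]] <- row
  }
  structure(list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
                 details = details),
            class = "segment_calls")
}

#' @export
print.segment_calls <- function(x, ...) {
  cat("<segment_calls>", nrow(x$table), "segments\n")
  print(x$table[, c("chrom", "start", "end", "n_probes", "cn_total",
                    "n_major", "n_minor", "mosaic_f")])
  invisible(x)
}

#' Export segment calls as JSON
#'
#' @param calls A `segment_calls` object or its `table`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
calls_to_json <- function(calls, path = NULL) {
  tab <- if (inherits(calls, "segment_calls")) calls$table else calls
  js <- jsonlite::toJSON(tab, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Export segment calls as a SEG-style TSV
#'
#' Coordinates are converted to 0-based half-open (`start0`), matching SEG
#' and BED conventions.
#'
#' @param calls A `segment_calls` object or its `table`.
#' @param path File path.
#' @export
write_seg <- function(calls, path) {
  tab <- if (inherits(calls, "segment_calls")) calls$table else calls
  out <- tab
  out$start0 <- out$start - 1
  out <- out[, c("chrom", "start0", "end", "n_probes", "mean_lrr", "bands",
                 "cn_total", "n_major", "n_minor", "mosaic_f", "ambiguous")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
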