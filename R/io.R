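#' Serialise a karyotype to JSON
#'
#' @param kt A [karyotype()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
karyotype_to_json <- function(kt, path = NULL) {
  obj <- list(name = kt$name,
              members = lapply(unname(kt$members), function(m) {
                list(name = m$name,
                     assume_telomere = m$assume_telomere,
                     segments = m$segments)
              }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a karyotype back from JSON
#' @param path File path or JSON string from [karyotype_to_json()].
#' @return A [karyotype()].
#' @export
karyotype_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  members <- lapply(seq_len(length(obj$members$name)), function(i) {
    derivative(obj$members$name[i],
               as.data.frame(obj$members$segments[[i]]),
               assume_telomere = obj$members$assume_telomere[[i]])
  })
  karyotype(obj$name, members)
}

#' Write derivative content as BED (0-based half-open)
#'
#' @param comp A `derivative_composition`, a list of them, or a content data
#'   frame with `chrom, start, end, copies`.
#' @param path File path.
#' @export
write_bed <- function(comp, path) {
  rows <- if (inherits(comp, "derivative_composition")) {
    cbind(name = comp$derivative, comp$content)
  } else if (is.data.frame(comp)) {
    cbind(name = "content", comp)
  } else {
    do.call(rbind, lapply(comp, function(x) cbind(name = x$derivative,
                                                  x$content)))
  }
  out <- data.frame(chrom = rows$chrom, start = rows$start - 1,
                    end = rows$end, name = rows$name, score = rows$copies)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' ISCN-flavoured one-line summary of a derivative
#'
#' Write-only shorthand: segments rendered as `chrom:start-end(hom,strand)`
#' joined by `::`.
#'
#' @param der A [derivative()].
#' @return Character string.
#' @export
derivative_summary <- function(der) {
  seg <- der$segments
  paste0(der$name, " = ",
         paste(sprintf("%s:%.0f-%.0f(%s%s)", seg$chrom, seg$start, seg$end,
                       seg$hom, ifelse(seg$strand == "-", ",inv", "")),
               collapse = "::"))
}

#' Human-readable karyotype / population summary
#'
#' @param x A [karyotype()] or [cell_population()].
#' @param path Optional file path; when `NULL` lines are returned.
#' @return Character vector of lines (invisibly when written).
#' @export
write_karyotype_summary <- function(x, path = NULL) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, paste0(...))
  summarise_kt <- function(kt, prefix = "") {
    add(prefix, kt$name, ": ", count_chromosomes(kt), " chromosomes")
    for (m in kt$members) add(prefix, "  ", derivative_summary(m))
  }
  if (inherits(x, "cell_population")) {
    add("cell population: ", length(x$clones), " clones, ",
        length(x$submosaics), " sub-mosaic event(s)")
    for (cl in x$clones) {
      add(sprintf("clone fraction %.3f", cl$fraction))
      summarise_kt(cl$karyotype, "  ")
    }
  } else {
    summarise_kt(x)
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Pipeline configuration
#'
#' Bundle of seeds, noise levels, inference limits and detector thresholds
#' used by the analysis drivers; round-trips through YAML.
#'
#' @param seed Integer master seed.
#' @param density_per_mb Probe density.
#' @param sigma_baf,sigma_lrr Array noise levels.
#' @param max_total,max_clones Inference limits.
#' @param min_band_sep Band clustering separation (0-0.5).
#' @param minority_share Centromere-capture minority share (0-1).
#' @param reduced_min FISH reduced-signal overlap threshold (0-1).
#' @param telomere_max_donor Telomere-capture maximum donor length (bp).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, density_per_mb = 30, sigma_baf = 0.03,
                            sigma_lrr = 0.15, max_total = 12, max_clones = 2,
                            min_band_sep = 0.08, minority_share = 0.25,
                            reduced_min = 0.1, telomere_max_donor = 1e7) {
  cfg <- list(seed = seed, density_per_mb = density_per_mb,
              sigma_baf = sigma_baf, sigma_lrr = sigma_lrr,
              max_total = max_total, max_clones = max_clones,
              min_band_sep = min_band_sep, minority_share = minority_share,
              reduced_min = reduced_min,
              telomere_max_donor = telomere_max_donor)
  stopifnot(cfg$density_per_mb > 0, cfg$sigma_baf >= 0, cfg$sigma_lrr >= 0,
            cfg$max_total >= 1, cfg$max_clones >= 1,
            cfg$min_band_sep > 0, cfg$min_band_sep <= 0.5,
            cfg$minority_share > 0, cfg$minority_share < 1,
            cfg$reduced_min > 0, cfg$reduced_min < 1)
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#' @param cfg A [pipeline_config()].
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
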