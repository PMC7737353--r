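#' Derivative composition from a known chromosome structure
#'
#' Collapses a [derivative()] into its multiset-level composition: content
#' intervals with copy counts, the centromere inventory, and end/telomere
#' provenance. This is the ground-truth counterpart of
#' [compose_derivatives()], which builds compositions from array calls plus
#' FISH evidence.
#'
#' @param der A [derivative()].
#' @param map A [genome_map()].
#' @param fraction Cell fraction carrying this derivative (used when
#'   population-level dosage sums are compared).
#' @return A list of class `derivative_composition`: `derivative`, `content`
#'   (`chrom, start, end, copies, hom`), `centromeres` (`chrom, copies,
#'   active`), `ends` (per-end terminal-segment provenance), `fraction`.
#' @export
as_composition <- function(der, map, fraction = 1) {
  seg <- der$segments
  key <- paste(seg$chrom, seg$start, seg$end, seg$hom)
  first <- !duplicated(key)
  content <- seg[first, c("chrom", "start", "end", "hom")]
  content$copies <- as.integer(table(key)[key[first]])
  rownames(content) <- NULL

  cen <- centromere(map, seg$chrom)
  hit <- interval_overlap(seg$start, seg$end, cen$cen_start, cen$cen_end) > 0
  cenrows <- seg[hit, , drop = FALSE]
  centromeres <- if (nrow(cenrows)) {
    agg <- stats::aggregate(cbind(copies = rep(1, nrow(cenrows)),
                                  active = as.integer(cenrows$cen_active)),
                            by = list(chrom = cenrows$chrom), FUN = sum)
    agg
  } else {
    data.frame(chrom = character(0), copies = integer(0),
               active = integer(0))
  }

  end_info <- function(i, outward_p) {
    s <- seg[i, ]
    st <- subtelomeres(map, s$chrom)
    side_start <- xor(outward_p, s$strand == "-")
    subtel <- if (side_start) s$start <= st$p[2] else s$end >= st$q[1]
    nb <- if (outward_p) {
      if (nrow(seg) > 1) seg$chrom[2] else NA_character_
    } else {
      if (nrow(seg) > 1) seg$chrom[nrow(seg) - 1] else NA_character_
    }
    list(chrom = s$chrom, start = s$start, end = s$end,
         subtelomeric = subtel, neighbour_chrom = nb)
  }
  structure(list(derivative = der$name, content = content,
                 centromeres = centromeres,
                 ends = list(p = end_info(1, TRUE),
                             q = end_info(nrow(seg), FALSE)),
                 fraction = fraction),
            class = "derivative_composition")
}

#' @export
print.derivative_composition <- function(x, ...) {
  cat("<composition>", x$derivative, "-", nrow(x$content), "content rows;",
      "centromeres:", if (nrow(x$centromeres))
        paste0(x$centromeres$chrom, collapse = ","), "\n")
  invisible(x)
}

#' Compose derivative content from segment calls and FISH evidence
#'
#' Distributes each called segment's (rounded) total copies across
#' derivatives proportionally to FISH copy-equivalents; copies not accounted
#' for by FISH go to an `"unplaced"` bucket, never dropped. FISH
#' copy-equivalents exceeding the called total produce a structured conflict
#' record rather than an error.
#'
#' @param calls A `segment_calls` object (or its `table`).
#' @param evidence List with `locus` (data frame `chrom, start, end, member,
#'   copies` from locus FISH of probes inside called segments) and
#'   `centromere` (data frame `chrom, member, copies, active`).
#' @param map A [genome_map()].
#' @param tol Copy-count slack before a conflict is recorded.
#' @return List of class `composition_set`: `compositions` (one
#'   `derivative_composition` per member with content), `unplaced` (content
#'   rows), `conflicts` (data frame).
#' @export
compose_derivatives <- function(calls, evidence, map, tol = 0.5) {
  tab <- if (inherits(calls, "segment_calls")) calls$table else calls
  members <- unique(evidence$locus$member)
  content <- stats::setNames(
    lapply(members, function(m) list()), members)
  unplaced <- list()
  conflicts <- list()
  for (i in seq_len(nrow(tab))) {
    s <- tab[i, ]
    if (is.na(s$cn_total)) next
    total <- round(s$cn_total)
    ev <- evidence$locus[evidence$locus$chrom == s$chrom &
                           evidence$locus$start >= s$start &
                           evidence$locus$end <= s$end, , drop = FALSE]
    placed <- 0
    if (nrow(ev)) {
      per <- vapply(split(ev$copies, ev$member), stats::median, 0)
      for (m in names(per)) {
        k <- round(per[[m]])
        if (k > 0) {
          content[[m]][[length(content[[m]]) + 1]] <-
            data.frame(chrom = s$chrom, start = s$start, end = s$end,
                       copies = k, stringsAsFactors = FALSE)
          placed <- placed + k
        }
      }
    }
    if (placed > total + tol) {
      conflicts[[length(conflicts) + 1]] <-
        data.frame(chrom = s$chrom, start = s$start, end = s$end,
                   called = total, fish = placed, stringsAsFactors = FALSE)
    } else if (placed < total) {
      unplaced[[length(unplaced) + 1]] <-
        data.frame(chrom = s$chrom, start = s$start, end = s$end,
                   copies = total - placed, stringsAsFactors = FALSE)
    }
  }
  comps <- lapply(members, function(m) {
    rows <- content[[m]]
    ct <- if (length(rows)) {
      do.call(rbind, c(rows, list(make.row.names = FALSE)))
    } else {
      data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                 copies = integer(0))
    }
    ct$hom <- rep(NA_character_, nrow(ct))
    cen <- evidence$centromere[evidence$centromere$member == m &
                                 evidence$centromere$copies > 0, , drop = FALSE]
    structure(list(derivative = m, content = ct,
                   centromeres = data.frame(chrom = cen$chrom,
                                            copies = cen$copies,
                                            active = cen$active),
                   ends = NULL, fraction = 1),
              class = "derivative_composition")
  })
  names(comps) <- members
  structure(list(compositions = comps,
                 unplaced = rbind_rows(unplaced),
                 conflicts = rbind_rows(conflicts)),
            class = "composition_set")
}

#' Detect centromere capture in a derivative composition
#'
#' Flags a derivative whose every centromere (i) comes from a chromosome
#' contributing less than `minority_share` of the derivative's total base
#' content, (ii) sits on a fragment confined to the donor centromere plus or
#' minus `window` (a short pericentromeric fragment rather than a
#' translocated arm), while (iii) the majority-content chromosome's own
#' centromere is absent.
#'
#' @param comp A `derivative_composition`.
#' @param map A [genome_map()].
#' @param minority_share Maximum content share of a capture donor.
#' @param window Pericentromeric confinement window (bp).
#' @param edge_tol Extra slack on the confinement test absorbing the
#'   probe-resolution uncertainty of called segment boundaries.
#' @return Data frame of capture calls (`derivative, kind, donor, seg_start,
#'   seg_end, donor_length, share`); zero rows when nothing is flagged.
#' @export
detect_centromere_capture <- function(comp, map, minority_share = 0.25,
                                      window = 3e6, edge_tol = 2.5e5) {
  ct <- comp$content
  if (is.null(ct) || nrow(ct) == 0) stop("empty composition")
  empty <- data.frame(derivative = character(0), kind = character(0),
                      donor = character(0), seg_start = numeric(0),
                      seg_end = numeric(0), donor_length = numeric(0),
                      share = numeric(0))
  cens <- comp$centromeres
  if (is.null(cens) || nrow(cens) == 0 || sum(cens$copies) == 0) return(empty)
  len_by <- tapply(ct$copies * (ct$end - ct$start + 1), ct$chrom, sum)
  total <- sum(len_by)
  majority <- names(len_by)[which.max(len_by)]
  if (majority %in% cens$chrom) return(empty)
  calls <- list()
  for (j in seq_len(nrow(cens))) {
    d <- cens$chrom[j]
    cen <- centromere(map, d)
    rows <- ct[ct$chrom == d &
                 interval_overlap(ct$start, ct$end, cen$cen_start,
                                  cen$cen_end) > 0, , drop = FALSE]
    if (nrow(rows) == 0) return(empty)  # donor extent unknown: no call
    confined <- all(rows$start >= cen$cen_start - window - edge_tol &
                      rows$end <= cen$cen_end + window + edge_tol)
    share <- if (d %in% names(len_by)) unname(len_by[d]) / total else 0
    if (!confined || share >= minority_share) return(empty)
    calls[[j]] <- data.frame(
      derivative = comp$derivative, kind = "centromere", donor = d,
      seg_start = min(rows$start), seg_end = max(rows$end),
      donor_length = sum(rows$end - rows$start + 1), share = share,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}

#' Detect telomere capture at the ends of a derivative composition
#'
#' Flags an end capped by a short subtelomeric fragment of a chromosome
#' different from the adjacent content's chromosome (the foreign subtelomere
#' acting as an array-visible proxy for a captured telomere). Requires end
#' provenance (available from [as_composition()] or adjacency hints);
#' compositions without end information yield no calls.
#'
#' @param comp A `derivative_composition`.
#' @param map A [genome_map()].
#' @param max_donor Maximum length (bp) of the capping fragment; longer
#'   foreign terminal segments are ordinary translocation arms.
#' @return Data frame of capture calls as in [detect_centromere_capture()].
#' @export
detect_telomere_capture <- function(comp, map, max_donor = 1e7) {
  empty <- data.frame(derivative = character(0), kind = character(0),
                      donor = character(0), seg_start = numeric(0),
                      seg_end = numeric(0), donor_length = numeric(0),
                      share = numeric(0))
  if (is.null(comp$ends)) return(empty)
  calls <- list()
  for (side in c("p", "q")) {
    e <- comp$ends[[side]]
    if (is.null(e) || !isTRUE(e$subtelomeric)) next
    len <- e$end - e$start + 1
    if (!is.na(e$neighbour_chrom) && e$neighbour_chrom != e$chrom &&
        len <= max_donor) {
      calls[[length(calls) + 1]] <- data.frame(
        derivative = comp$derivative, kind = "telomere", donor = e$chrom,
        seg_start = e$start, seg_end = e$end, donor_length = len,
        share = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) return(empty)
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}

#' Export a composition (and optional capture calls) as JSON or text
#'
#' @param comp A `derivative_composition`.
#' @param captures Optional capture-call data frame to embed.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @export
composition_to_json <- function(comp, captures = NULL, path = NULL) {
  obj <- list(derivative = comp$derivative, fraction = comp$fraction,
              content = comp$content, centromeres = comp$centromeres,
              ends = comp$ends)
  if (!is.null(captures)) obj$captures <- captures
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname composition_to_json
#' @return `composition_report()` returns character lines.
#' @export
composition_report <- function(comp, captures = NULL) {
  lines <- c(sprintf("derivative %s (fraction %.3f)", comp$derivative,
                     comp$fraction))
  for (i in seq_len(nrow(comp$content))) {
    ct <- comp$content[i, ]
    lines <- c(lines, sprintf("  %sx %s:%.0f-%.0f%s", ct$copies, ct$chrom,
                              ct$start, ct$end,
                              if (!is.na(ct$hom)) paste0(" (hom ", ct$hom, ")")
                              else ""))
  }
  if (nrow(comp$centromeres)) {
    lines <- c(lines, paste0("  centromeres: ",
                             paste(comp$centromeres$chrom, collapse = ", ")))
  }
  if (!is.null(captures) && nrow(captures)) {
    lines <- c(lines, sprintf("  %s capture from chromosome %s (%.1f Mb)",
                              captures$kind, captures$donor,
                              captures$donor_length / 1e6))
  }
  lines
}

#' Solve homologue-label assignment for one chromosome
#'
#' Exhaustive search over assignments of the two homologue labels to each
#' composition's content of the chromosome, keeping assignments whose
#' per-interval label dosage sums match the inferred `(n_major, n_minor)`
#' calls within tolerance.
#'
#' @param chromosome Chromosome name.
#' @param calls A `segment_calls` object (or table) with `n_major`,
#'   `n_minor` for intervals of the chromosome.
#' @param compositions List of `derivative_composition`s containing the
#'   chromosome (each with a `fraction`).
#' @param tol Allowed absolute deviation per interval sum.
#' @return List of class `homologue_solution`: `pieces` (data frame with
#'   `derivative, chrom, start, end, copies, fraction, label` — label `NA`
#'   when ambiguous), `status` (`"unique"`, `"ambiguous"` or
#'   `"inconsistent"`), `n_solutions`, and `violations` (intervals no
#'   assignment could satisfy, for inconsistent cases).
#' @export
solve_homologue_assignment <- function(chromosome, calls, compositions,
                                       tol = 0.3) {
  tab <- if (inherits(calls, "segment_calls")) calls$table else calls
  tab <- tab[tab$chrom == chromosome & !is.na(tab$n_major), , drop = FALSE]
  pieces <- list()
  for (comp in compositions) {
    ct <- comp$content[comp$content$chrom == chromosome, , drop = FALSE]
    for (i in seq_len(nrow(ct))) {
      pieces[[length(pieces) + 1]] <-
        data.frame(derivative = comp$derivative, chrom = chromosome,
                   start = ct$start[i], end = ct$end[i],
                   copies = ct$copies[i], fraction = comp$fraction,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(pieces) == 0) stop("chromosome absent from all compositions")
  pieces <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  P <- nrow(pieces)
  if (P > 16) stop("too many content pieces for exhaustive assignment")

  # overlap matrix: piece dosage contribution to each called interval
  contrib <- matrix(0, nrow(tab), P)
  for (i in seq_len(nrow(tab))) {
    ov <- interval_overlap(pieces$start, pieces$end, tab$start[i],
                           tab$end[i])
    frac <- ov / (tab$end[i] - tab$start[i] + 1)
    contrib[i, ] <- ifelse(frac > 0.5, pieces$copies * pieces$fraction, 0)
  }
  target <- cbind(tab$n_major, tab$n_minor)

  best_cost <- Inf
  solutions <- list()
  for (mask in 0:(2^(P - 1) - 1)) {         # piece 1 pinned to label 1
    lab <- c(1L, as.integer(intToBits(mask))[seq_len(P - 1)] + 1L)
    s1 <- as.vector(contrib %*% (lab == 1L))
    s2 <- as.vector(contrib %*% (lab == 2L))
    dev <- pmin(abs(s1 - target[, 1]) + abs(s2 - target[, 2]),
                abs(s1 - target[, 2]) + abs(s2 - target[, 1]))
    cost <- sum(dev)
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      solutions <- list(lab)
    } else if (cost <= best_cost + 1e-9) {
      solutions <- c(solutions, list(lab))
    }
  }
  feasible <- best_cost <= tol * nrow(tab)
  status <- if (!feasible) {
    "inconsistent"
  } else if (length(solutions) == 1) {
    "unique"
  } else {
    "ambiguous"
  }
  lab <- solutions[[1]]
  # label only pieces on which every optimal assignment agrees
  agree <- Reduce(`&`, lapply(solutions, function(s) s == lab))
  pieces$label <- ifelse(agree & feasible, lab, NA_integer_)
  violations <- if (!feasible) {
    s1 <- as.vector(contrib %*% (lab == 1L))
    s2 <- as.vector(contrib %*% (lab == 2L))
    dev <- pmin(abs(s1 - target[, 1]) + abs(s2 - target[, 2]),
                abs(s1 - target[, 2]) + abs(s2 - target[, 1]))
    tab[dev > tol, c("chrom", "start", "end"), drop = FALSE]
  } else {
    NULL
  }
  structure(list(pieces = pieces, status = status,
                 n_solutions = length(solutions), solutions = solutions,
                 violations = violations),
            class = "homologue_solution")
}

#' Classify whether two derivatives carry the same homologue of a chromosome
#'
#' @param compA,compB `derivative_composition`s containing the chromosome.
#' @param chromosome Chromosome name.
#' @param calls Segment calls for the chromosome (see
#'   [solve_homologue_assignment()]).
#' @param other_compositions Additional compositions constraining the
#'   assignment (e.g. the normal homologues).
#' @return `"same"`, `"different"` or `"ambiguous"`.
#' @export
classify_rearrangement_homologues <- function(compA, compB, chromosome,
                                              calls,
                                              other_compositions = list()) {
  has <- function(comp) any(comp$content$chrom == chromosome)
  if (!has(compA) || !has(compB)) {
    stop("chromosome ", chromosome, " absent from a composition")
  }
  if (identical(compA$derivative, compB$derivative)) return("same")
  sol <- solve_homologue_assignment(
    chromosome, calls, c(list(compA, compB), other_compositions))
  if (sol$status == "inconsistent") return("ambiguous")
  iA <- which(sol$pieces$derivative == compA$derivative)
  iB <- which(sol$pieces$derivative == compB$derivative)
  # the same/different relation may be determined even when the absolute
  # labels are not: evaluate it in every optimal assignment
  rels <- vapply(sol$solutions, function(s) {
    la <- unique(s[iA])
    lb <- unique(s[iB])
    if (length(la) != 1 || length(lb) != 1) return(NA)
    la == lb
  }, TRUE)
  if (anyNA(rels) || length(unique(rels)) != 1) return("ambiguous")
  if (rels[1]) "same" else "different"
}
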