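#' Construct a rearrangement event
#'
#' Supported kinds:
#' \describe{
#'   \item{deletion}{Remove reference interval `start`-`end` (on `chrom`) from
#'     member `member`.}
#'   \item{tandem_duplication}{Duplicate interval in place (head-to-tail).}
#'   \item{inverted_duplication}{Duplicate interval in place, inverted.}
#'   \item{amplification}{Insert `count - 1` extra copies of the interval
#'     (`count >= 2`), inverted copies when `inverted = TRUE`.}
#'   \item{balanced_translocation}{Exchange the `side`-distal portion of
#'     `member` cut after `pos` on `chrom` with the `side2`-distal portion of
#'     `member2` cut after `pos2` on `chrom2`; base content is conserved.}
#'   \item{unbalanced_translocation}{`member` (recipient) loses its
#'     `side`-distal portion (unless `recipient_loss = FALSE`) and gains the
#'     `side2`-distal portion of `member2` (donor). With `duplicative = TRUE`
#'     the donor keeps its material (a copied capture); otherwise the donor is
#'     truncated.}
#'   \item{segment_capture}{Duplicatively copy the interval `start2`-`end2` of
#'     `chrom2` from member `member2` (first matching segment copy) into
#'     `member`, attached at `side` (`"p"`/`"q"`) or after row `after` of the
#'     member's segment table, with `orientation` `"+"` or `"-"`. Models
#'     captured fragments (telomere/centromere capture, insertions) without
#'     removing material from the donor.}
#'   \item{whole_genome_duplication}{Add one genotype-identical extra copy of
#'     each member named in `members` (a designated haploid complement).}
#'   \item{chromosome_gain}{Add a genotype-identical copy of `member`.}
#'   \item{chromosome_loss}{Remove `member`.}
#' }
#'
#' Cut semantics: a cut at `pos` falls between reference positions `pos` and
#' `pos + 1`; a `"p"` portion is everything member-ordered before the cut, a
#' `"q"` portion everything after. Deletion intervals are 1-based inclusive.
#'
#' @param kind Event kind (see above).
#' @param ... Kind-specific fields: `member`, `chrom`, `start`, `end`, `pos`,
#'   `side`, `member2`, `chrom2`, `pos2`, `side2`, `count`, `inverted`,
#'   `duplicative`, `recipient_loss`, `members`, `founder_suffix`,
#'   `piece_cen_active`, `new_name`, `new_name2`.
#' @return An object of class `rearrangement_event`.
#' @export
rearrangement_event <- function(kind, ...) {
  kinds <- c("deletion", "tandem_duplication", "inverted_duplication",
             "amplification", "balanced_translocation",
             "unbalanced_translocation", "segment_capture",
             "whole_genome_duplication", "chromosome_gain", "chromosome_loss")
  kind <- match.arg(kind, kinds)
  ev <- list(kind = kind, ...)
  if (kind == "amplification" && (is.null(ev$count) || ev$count < 2)) {
    stop("amplification requires count >= 2")
  }
  structure(ev, class = "rearrangement_event")
}

# reverse a block of segment rows (physical inversion)
flip_rows <- function(df) {
  if (nrow(df) == 0) return(df)
  df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
  df$strand <- ifelse(df$strand == "+", "-", "+")
  rownames(df) <- NULL
  df
}

# split one segment row at the cut after reference position `pos`;
# returns list(left, right) in member order (either may have 0 rows)
split_row <- function(row, pos) {
  if (row$strand == "+") {
    left <- row; left$end <- min(row$end, pos)
    right <- row; right$start <- max(row$start, pos + 1)
  } else {
    left <- row; left$start <- max(row$start, pos + 1)
    right <- row; right$end <- min(row$end, pos)
  }
  list(left = left[left$end >= left$start, , drop = FALSE],
       right = right[right$end >= right$start, , drop = FALSE])
}

# split a member's segment table at a (chrom, pos) cut into member-ordered
# left/right parts; the cut must fall strictly inside exactly one segment or
# on a segment boundary
split_member <- function(seg, chrom, pos) {
  hit <- which(seg$chrom == chrom & seg$start <= pos & seg$end >= pos + 1)
  if (length(hit) > 1) {
    stop("ambiguous cut: position ", chrom, ":", pos,
         " lies inside several segments of the member")
  }
  if (length(hit) == 1) {
    sp <- split_row(seg[hit, , drop = FALSE], pos)
    left <- rbind(seg[seq_len(hit - 1), , drop = FALSE], sp$left)
    right <- rbind(sp$right,
                   seg[seq_len(nrow(seg)) > hit, , drop = FALSE])
    return(list(left = left, right = right))
  }
  # boundary cut: between rows i and i+1 where row i ends at pos
  edge <- which(seg$chrom == chrom &
                  ((seg$strand == "+" & seg$end == pos) |
                     (seg$strand == "-" & seg$start == pos + 1)))
  if (length(edge) != 1) {
    stop("cut position ", chrom, ":", pos, " not inside the member")
  }
  list(left = seg[seq_len(edge), , drop = FALSE],
       right = seg[seq_len(nrow(seg)) > edge, , drop = FALSE])
}

# remove reference interval [s, e] on chrom from every overlapping segment row
delete_interval <- function(seg, chrom, s, e) {
  out <- list()
  for (i in seq_len(nrow(seg))) {
    row <- seg[i, , drop = FALSE]
    if (row$chrom != chrom || row$end < s || row$start > e) {
      out[[length(out) + 1]] <- row
      next
    }
    lo <- row; lo$end <- s - 1          # retained low-coordinate piece
    hi <- row; hi$start <- e + 1        # retained high-coordinate piece
    keep <- list(lo[lo$end >= lo$start, , drop = FALSE],
                 hi[hi$end >= hi$start, , drop = FALSE])
    if (row$strand == "-") keep <- rev(keep)
    for (k in keep) if (nrow(k)) out[[length(out) + 1]] <- k
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# extract member-ordered rows covering reference interval [s, e] on chrom;
# occurrence = NULL takes all overlapping rows, k takes only the k-th
extract_interval <- function(seg, chrom, s, e, occurrence = NULL) {
  out <- list()
  hit <- 0L
  for (i in seq_len(nrow(seg))) {
    row <- seg[i, , drop = FALSE]
    if (row$chrom != chrom || row$end < s || row$start > e) next
    hit <- hit + 1L
    if (!is.null(occurrence) && hit != occurrence) next
    piece <- row
    piece$start <- max(row$start, s)
    piece$end <- min(row$end, e)
    out[[length(out) + 1]] <- piece
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

get_member <- function(kt, name) {
  m <- kt$members[[name]]
  if (is.null(m)) stop("no member named '", name, "' in karyotype ", kt$name)
  m
}

check_coord <- function(map, chrom, pos) {
  if (is.null(map)) return(invisible())
  len <- chrom_length(map, chrom)
  if (any(pos < 1 | pos > len)) {
    stop("coordinate outside chromosome ", chrom, ": ",
         paste(pos[pos < 1 | pos > len], collapse = ", "))
  }
  invisible()
}

# portion of a member distal on `side` of cut (chrom, pos), plus the remainder
take_portion <- function(seg, chrom, pos, side) {
  sp <- split_member(seg, chrom, pos)
  if (side == "p") {
    list(portion = sp$left, rest = sp$right)
  } else {
    list(portion = sp$right, rest = sp$left)
  }
}

# orient a donor portion for attachment: the attached block must present its
# cut edge toward the join. `at_left = TRUE` when the block becomes the new
# p-terminal part (its cut edge must be its member-right edge).
orient_portion <- function(portion, side2, at_left) {
  flip <- if (at_left) side2 == "q" else side2 == "p"
  if (flip) flip_rows(portion) else portion
}

replace_member <- function(kt, name, der) {
  kt$members[[name]] <- der
  names(kt$members)[names(kt$members) == name] <- der$name
  kt
}

#' Apply a rearrangement event to a karyotype
#'
#' @param kt A [karyotype()].
#' @param event A [rearrangement_event()].
#' @param map Optional [genome_map()] for coordinate validation.
#' @return A new [karyotype()]; the input is not modified.
#' @export
apply_event <- function(kt, event, map = NULL) {
  stopifnot(inherits(kt, "karyotype"), inherits(event, "rearrangement_event"))
  ev <- event
  rename <- function(der) {
    if (!is.null(ev$new_name)) der$name <- ev$new_name
    der
  }

  if (ev$kind == "chromosome_loss") {
    m <- get_member(kt, ev$member)
    kt$members[[ev$member]] <- NULL
    return(kt)
  }

  if (ev$kind == "chromosome_gain") {
    m <- get_member(kt, ev$member)
    m2 <- rename(m)
    if (!is.null(ev$founder_suffix)) {
      m2$segments$founder <- paste0(m2$segments$hom, ev$founder_suffix)
    }
    kt$members <- c(kt$members, list(m2))
    names(kt$members) <- make.unique(
      vapply(kt$members, `[[`, "", "name"), sep = "#")
    return(kt)
  }

  if (ev$kind == "whole_genome_duplication") {
    add <- list()
    for (k in seq_along(ev$members)) {
      m <- get_member(kt, ev$members[[k]])
      m$segments$founder <- paste0(
        m$segments$hom,
        if (is.null(ev$founder_suffix)) "2" else ev$founder_suffix)
      if (!is.null(ev$copy_names)) m$name <- ev$copy_names[[k]]
      add <- c(add, list(m))
    }
    kt$members <- c(kt$members, add)
    names(kt$members) <- make.unique(
      vapply(kt$members, `[[`, "", "name"), sep = "#")
    return(kt)
  }

  if (ev$kind == "deletion") {
    check_coord(map, ev$chrom, c(ev$start, ev$end))
    m <- get_member(kt, ev$member)
    seg <- delete_interval(m$segments, ev$chrom, ev$start, ev$end)
    if (is.null(seg) || nrow(seg) == 0) {
      kt$members[[ev$member]] <- NULL
      return(kt)
    }
    m$segments <- seg
    return(replace_member(kt, ev$member, rename(m)))
  }

  if (ev$kind %in% c("tandem_duplication", "inverted_duplication",
                     "amplification")) {
    check_coord(map, ev$chrom, c(ev$start, ev$end))
    m <- get_member(kt, ev$member)
    seg <- m$segments
    piece <- extract_interval(seg, ev$chrom, ev$start, ev$end, occurrence = 1)
    if (is.null(piece) || nrow(piece) == 0) {
      stop("duplication interval not present in member ", ev$member)
    }
    n_extra <- switch(ev$kind,
                      tandem_duplication = 1L,
                      inverted_duplication = 1L,
                      amplification = as.integer(ev$count) - 1L)
    invert <- ev$kind == "inverted_duplication" || isTRUE(ev$inverted)
    copies <- lapply(seq_len(n_extra), function(k) {
      if (invert && k %% 2 == 1) flip_rows(piece) else piece
    })
    # insert the copies at the cut immediately after the duplicated interval
    sp <- split_member(seg, ev$chrom, ev$end)
    m$segments <- do.call(rbind, c(
      list(sp$left), copies, list(sp$right, make.row.names = FALSE)))
    return(replace_member(kt, ev$member, rename(m)))
  }

  if (ev$kind == "balanced_translocation") {
    check_coord(map, ev$chrom, ev$pos)
    check_coord(map, ev$chrom2, ev$pos2)
    a <- get_member(kt, ev$member)
    b <- get_member(kt, ev$member2)
    pa <- take_portion(a$segments, ev$chrom, ev$pos, ev$side)
    pb <- take_portion(b$segments, ev$chrom2, ev$pos2, ev$side2)
    join <- function(rest, portion, side_lost, side_src) {
      if (side_lost == "p") {
        rbind(orient_portion(portion, side_src, at_left = TRUE), rest,
              make.row.names = FALSE)
      } else {
        rbind(rest, orient_portion(portion, side_src, at_left = FALSE),
              make.row.names = FALSE)
      }
    }
    a$segments <- join(pa$rest, pb$portion, ev$side, ev$side2)
    b$segments <- join(pb$rest, pa$portion, ev$side2, ev$side)
    if (!is.null(ev$new_name)) a$name <- ev$new_name
    if (!is.null(ev$new_name2)) b$name <- ev$new_name2
    kt <- replace_member(kt, ev$member, a)
    kt <- replace_member(kt, ev$member2, b)
    return(kt)
  }

  if (ev$kind == "segment_capture") {
    check_coord(map, ev$chrom2, c(ev$start2, ev$end2))
    a <- get_member(kt, ev$member)
    b <- get_member(kt, ev$member2)
    piece <- extract_interval(b$segments, ev$chrom2, ev$start2, ev$end2,
                              occurrence = if (is.null(ev$occurrence)) 1
                                           else ev$occurrence)
    if (is.null(piece) || nrow(piece) == 0) {
      stop("capture interval not present in donor ", ev$member2)
    }
    if (identical(ev$orientation, "-")) piece <- flip_rows(piece)
    if (!is.null(ev$piece_cen_active)) piece$cen_active <- ev$piece_cen_active
    seg <- a$segments
    at <- if (!is.null(ev$after)) {
      ev$after
    } else if (identical(ev$side, "p")) 0L else nrow(seg)
    a$segments <- rbind(seg[seq_len(nrow(seg)) <= at, , drop = FALSE],
                        piece,
                        seg[seq_len(nrow(seg)) > at, , drop = FALSE],
                        make.row.names = FALSE)
    return(replace_member(kt, ev$member, rename(a)))
  }

  if (ev$kind == "unbalanced_translocation") {
    check_coord(map, ev$chrom, ev$pos)
    check_coord(map, ev$chrom2, ev$pos2)
    a <- get_member(kt, ev$member)
    b <- get_member(kt, ev$member2)
    pb <- take_portion(b$segments, ev$chrom2, ev$pos2, ev$side2)
    piece <- pb$portion
    if (!is.null(ev$piece_cen_active)) piece$cen_active <- ev$piece_cen_active
    loss <- !identical(ev$recipient_loss, FALSE)
    if (loss) {
      pa <- take_portion(a$segments, ev$chrom, ev$pos, ev$side)
      rest <- pa$rest
    } else {
      rest <- a$segments
    }
    if (ev$side == "p") {
      a$segments <- rbind(orient_portion(piece, ev$side2, at_left = TRUE),
                          rest, make.row.names = FALSE)
    } else {
      a$segments <- rbind(rest,
                          orient_portion(piece, ev$side2, at_left = FALSE),
                          make.row.names = FALSE)
    }
    kt <- replace_member(kt, ev$member, rename(a))
    if (!isTRUE(ev$duplicative)) {
      if (nrow(pb$rest) == 0) {
        kt$members[[ev$member2]] <- NULL
      } else {
        b$segments <- pb$rest
        kt <- replace_member(kt, ev$member2, b)
      }
    }
    return(kt)
  }

  stop("unhandled event kind: ", ev$kind)
}

#' Apply a list of events in order
#' @inheritParams apply_event
#' @param events List of [rearrangement_event()]s.
#' @export
apply_events <- function(kt, events, map = NULL) {
  for (ev in events) kt <- apply_event(kt, ev, map)
  kt
}
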