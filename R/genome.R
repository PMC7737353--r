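#' Built-in human genome map (GRCh38 scale)
#'
#' Chromosome lengths and centromere intervals are a simplified built-in table
#' at roughly GRCh38 scale; coordinates are 1-based inclusive throughout the
#' package.  Acrocentric short arms are retained in the coordinate system, so
#' the standard subtelomere rule applies at both ends of every chromosome.
#'
#' @param subtelomere_bp Width of the subtelomere window applied at both ends
#'   of each chromosome, in bp.  A terminal segment reaching into this window
#'   on its outward-facing side is taken as evidence of a telomere.
#' @param chromosomes Optional character vector restricting the map to a
#'   subset of chromosomes (used by the scenario generator).
#' @return An object of class `genome_map`: a data frame with columns
#'   `chrom`, `length`, `cen_start`, `cen_end`, with the subtelomere width in
#'   `attr(, "subtelomere")`.
#' @export
genome_map <- function(subtelomere_bp = 5e5, chromosomes = NULL) {
  tab <- data.frame(
    chrom = c(as.character(1:22), "X", "Y"),
    length = c(
      248956422L, 242193529L, 198295559L, 190214555L, 181538259L,
      170805979L, 159345973L, 145138636L, 138394717L, 133797422L,
      135086622L, 133275309L, 114364328L, 107043718L, 101991189L,
      90338345L, 83257441L, 80373285L, 58617616L, 64444167L,
      46709983L, 50818468L, 156040895L, 57227415L
    ),
    cen_start = c(
      122026459L, 92188145L, 90772458L, 49712061L, 46485900L,
      58553888L, 58169653L, 44033744L, 43389635L, 39686682L,
      51078348L, 34769407L, 16000000L, 16000000L, 17083673L,
      36311158L, 22813679L, 15460899L, 24498980L, 26436232L,
      10864560L, 12954788L, 58605579L, 10316944L
    ),
    cen_end = c(
      125184587L, 94090557L, 93655574L, 51743951L, 50059807L,
      60999388L, 61528020L, 45877265L, 45518558L, 41593521L,
      54425074L, 37185252L, 18051248L, 18173523L, 19725254L,
      38265669L, 26616164L, 20861206L, 27190874L, 30038348L,
      12915808L, 15054318L, 62412542L, 10544039L
    ),
    stringsAsFactors = FALSE
  )
  if (!is.null(chromosomes)) {
    miss <- setdiff(chromosomes, tab$chrom)
    if (length(miss)) stop("unknown chromosome(s): ", paste(miss, collapse = ", "))
    tab <- tab[match(chromosomes, tab$chrom), , drop = FALSE]
    rownames(tab) <- NULL
  }
  stopifnot(all(tab$cen_start > 1), all(tab$cen_end < tab$length),
            subtelomere_bp < min(tab$length) / 2)
  attr(tab, "subtelomere") <- as.numeric(subtelomere_bp)
  class(tab) <- c("genome_map", "data.frame")
  tab
}

map_chrom <- function(map, chrom) {
  i <- match(as.character(chrom), map$chrom)
  if (any(is.na(i))) {
    stop("chromosome not in genome map: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  i
}

#' Chromosome length lookup
#' @param map A `genome_map`.
#' @param chrom Chromosome name(s).
#' @return Numeric vector of lengths in bp.
#' @export
chrom_length <- function(map, chrom) map$length[map_chrom(map, chrom)]

#' Centromere interval lookup
#' @inheritParams chrom_length
#' @return Data frame with `cen_start`, `cen_end`.
#' @export
centromere <- function(map, chrom) {
  map[map_chrom(map, chrom), c("cen_start", "cen_end")]
}

#' Subtelomere windows of a chromosome
#' @inheritParams chrom_length
#' @return A list with `p = c(start, end)` and `q = c(start, end)` windows.
#' @export
subtelomeres <- function(map, chrom) {
  len <- chrom_length(map, chrom)
  st <- attr(map, "subtelomere")
  list(p = c(1, st), q = c(len - st + 1, len))
}

# Overlap length of [s1,e1] and [s2,e2], 1-based inclusive; 0 when disjoint.
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

# rbind a list of data-frame rows; NULL when the list is empty
rbind_rows <- function(lst) {
  lst <- lst[!vapply(lst, is.null, TRUE)]
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
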