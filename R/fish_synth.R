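#' Define FISH probes
#'
#' @param name Probe name (e.g. BAC clone id or centromere probe id).
#' @param kind `"locus"` or `"centromere"`.
#' @param chrom Target chromosome.
#' @param start,end Target interval (locus probes; ignored for centromere
#'   probes).
#' @param band Cytogenetic band label (annotation only).
#' @return Data frame of class `fish_probes`.
#' @export
fish_probes <- function(name, kind, chrom, start = NA, end = NA, band = "") {
  df <- data.frame(name = name, kind = kind, chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   band = band, stringsAsFactors = FALSE)
  stopifnot(all(df$kind %in% c("locus", "centromere")))
  class(df) <- c("fish_probes", "data.frame")
  df
}

fish_symbol <- function(copies, reduced) {
  ifelse(copies > 0,
         paste0(strrep("+", copies), ifelse(reduced, "(+)", "")),
         ifelse(reduced, "(+)", "–"))
}

#' Simulate metaphase locus FISH on a karyotype
#'
#' For each karyotype member, the copy-equivalent signal `k` is the number of
#' segment copies fully containing the probe interval (signal intensity is
#' compared against the one-copy signal on a normal chromosome, so `k` "+"
#' symbols mean a k-fold signal; tandem copies on one derivative merge into
#' one bright signal). A segment covering at least `reduced_min` of the probe
#' but not all of it produces a reduced-intensity "(+)" signal.
#'
#' @param probe One-row locus [fish_probes()] entry.
#' @param kt A [karyotype()].
#' @param map A [genome_map()].
#' @param reduced_min Minimum overlap fraction of the probe interval for a
#'   reduced signal; smaller overlaps score as absent.
#' @return Data frame `member, copies, reduced, symbol`.
#' @export
simulate_locus_fish <- function(probe, kt, map, reduced_min = 0.1) {
  stopifnot(nrow(probe) == 1, probe$kind == "locus")
  map_chrom(map, probe$chrom)  # reference check
  plen <- probe$end - probe$start + 1
  out <- lapply(kt$members, function(m) {
    seg <- m$segments
    sel <- seg$chrom == probe$chrom
    full <- sum(sel & seg$start <= probe$start & seg$end >= probe$end)
    ov <- interval_overlap(seg$start[sel], seg$end[sel], probe$start,
                           probe$end)
    partial <- sum(ov >= reduced_min * plen & ov < plen)
    data.frame(member = m$name, copies = full, reduced = partial > 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$symbol <- fish_symbol(res$copies, res$reduced)
  res
}

#' Simulate metaphase centromere FISH on a karyotype
#'
#' Counts, per member, segments overlapping the named chromosome's centromere
#' interval (a centromere probe hybridises whether or not the centromere is
#' active; activity is reported separately).
#'
#' @param chrom Chromosome whose centromere probe is hybridised.
#' @param kt A [karyotype()].
#' @param map A [genome_map()].
#' @return Data frame `member, copies, active, symbol`.
#' @export
simulate_centromere_fish <- function(chrom, kt, map) {
  cen <- centromere(map, chrom)
  out <- lapply(kt$members, function(m) {
    seg <- m$segments
    hit <- seg$chrom == as.character(chrom) &
      interval_overlap(seg$start, seg$end, cen$cen_start, cen$cen_end) > 0
    data.frame(member = m$name, copies = sum(hit),
               active = sum(hit & seg$cen_active), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res$symbol <- fish_symbol(res$copies, FALSE)
  res
}

#' Simulate an interphase FISH presence count
#'
#' Cells are drawn from the clone/sub-mosaic mixture; a cell scores present
#' when the probe interval is fully contained in at least one segment of the
#' queried member (or, with `member = NULL`, anywhere in the cell's
#' karyotype). Sampling is binomial and seed-reproducible.
#'
#' @param probe One-row locus [fish_probes()] entry.
#' @param pop A [cell_population()].
#' @param n_cells Number of interphase nuclei scored.
#' @param seed Integer seed.
#' @param member Optional member name restricting presence scoring to one
#'   derivative (metaphase-informed scoring).
#' @return List `n_present`, `n_absent`, `true_fraction`.
#' @export
simulate_interphase_fish <- function(probe, pop, n_cells, seed = 1,
                                     member = NULL) {
  stopifnot(n_cells >= 1, nrow(probe) == 1, probe$kind == "locus")
  p <- 0
  for (e in effective_clones(pop)) {
    members <- if (is.null(member)) e$karyotype$members
               else e$karyotype$members[member]
    present <- any(vapply(members, function(m) {
      if (is.null(m)) return(FALSE)
      seg <- m$segments
      any(seg$chrom == probe$chrom & seg$start <= probe$start &
            seg$end >= probe$end)
    }, TRUE))
    if (present) p <- p + e$fraction
  }
  n_present <- with_seed(seed, stats::rbinom(1, n_cells, p))
  list(n_present = n_present, n_absent = n_cells - n_present,
       true_fraction = p)
}

#' Render a FISH result table for selected derivatives
#'
#' One row per probe, one symbol column per selected member, mirroring the
#' layout of targeted-FISH summary tables ("+" per copy-equivalent, "(+)"
#' reduced signal, en dash absent).
#'
#' @param probes A [fish_probes()] table.
#' @param kt A [karyotype()].
#' @param map A [genome_map()].
#' @param members Character vector of member names (columns).
#' @return Data frame `probe, band, chrom, start, end` plus one column per
#'   member.
#' @export
fish_table <- function(probes, kt, map, members) {
  out <- probes[, c("name", "band", "chrom", "start", "end")]
  names(out)[1] <- "probe"
  for (mn in members) out[[mn]] <- NA_character_
  for (i in seq_len(nrow(probes))) {
    p <- probes[i, , drop = FALSE]
    res <- if (p$kind == "centromere") {
      simulate_centromere_fish(p$chrom, kt, map)
    } else {
      simulate_locus_fish(p, kt, map)
    }
    for (mn in members) out[i, mn] <- res$symbol[res$member == mn]
  }
  out
}

#' Write a FISH table as TSV
#' @param tab Output of [fish_table()].
#' @param path File path.
#' @export
write_fish_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Targeted FISH probe panel used for the U937 fixture
#'
#' BAC and centromere probes with GRCh38 coordinates covering the chromosome
#' 5, 7, 8, 11, 15, 16 and 20 regions interrogated in the fixture.
#'
#' @return A [fish_probes()] table.
#' @export
u937_fish_probes <- function() {
  rbind(
    fish_probes("D11Z1", "centromere", "11", band = "11cen"),
    fish_probes("KMT2A", "locus", "11", 118436490, 118525221, "11q23.3"),
    fish_probes("RP11-754N12", "locus", "11", 128311087, 128485203, "11q24.3"),
    fish_probes("FLI1", "locus", "11", 128694094, 128812000, "11q24.3"),
    fish_probes("MYH11", "locus", "16", 15703135, 15857030, "16p13.11"),
    fish_probes("RP11-597G23", "locus", "15", 37089671, 37297139, "15q14"),
    fish_probes("RP11-607G03", "locus", "15", 51495000, 51629079, "15q21.2"),
    fish_probes("RP11-366L09", "locus", "15", 60041031, 60218374, "15q22.2"),
    fish_probes("RP11-775C24", "locus", "15", 80970069, 81137763, "15q25.1"),
    fish_probes("RP11-500O11", "locus", "20", 22409751, 22462800, "20p11.21"),
    fish_probes("RP11-755M18", "locus", "20", 22756464, 22940284, "20p11.21"),
    fish_probes("RP11-218C14", "locus", "20", 23530430, 23671508, "20p11.21"),
    fish_probes("RP11-717H21", "locus", "20", 24130923, 24332313, "20p11.21"),
    fish_probes("RP11-580L12", "locus", "20", 24568986, 24763965, "20p11.21"),
    fish_probes("RP11-156D15", "locus", "20", 25124608, 25306738, "20p11.21"),
    fish_probes("RP11-384D7", "locus", "20", 25306022, 25435715, "20p11.21"),
    fish_probes("RP11-269F15", "locus", "20", 25925848, 26084581, "20p11.1"),
    fish_probes("D20Z1", "centromere", "20", band = "20cen"),
    fish_probes("RP11-602P9", "locus", "20", 31245645, 31409837, "20q11.21"),
    fish_probes("RP11-802B20", "locus", "20", 31435456, 31585732, "20q11.21"),
    fish_probes("RP11-363M16", "locus", "20", 31483476, 31684958, "20q11.21"),
    fish_probes("RP11-702M08", "locus", "20", 31592650, 31760766, "20q11.21"),
    fish_probes("RP11-243J16", "locus", "20", 31705215, 31874074, "20q11.21"),
    fish_probes("RP11-71I02", "locus", "20", 31902727, 32053101, "20q11.21"),
    fish_probes("RP11-620H13", "locus", "20", 31935170, 32131327, "20q11.21"),
    fish_probes("RP11-483M19", "locus", "20", 32022592, 32204778, "20q11.21"),
    fish_probes("RP11-724J12", "locus", "20", 32385910, 32580055, "20q11.21"),
    fish_probes("RP11-49G10", "locus", "20", 33132629, 33305883, "20q11.21"),
    fish_probes("RP11-120F10", "locus", "20", 33458641, 33609412, "20q11.22"),
    fish_probes("RP11-541L2", "locus", "20", 33747044, 33935043, "20q11.22"),
    fish_probes("RP11-642P13", "locus", "20", 34110945, 34261427, "20q11.22"),
    fish_probes("D20S108", "locus", "20", 42201817, 42202000, "20q12"),
    fish_probes("RP11-185I4", "locus", "5", 50139424, 50285096, "5q11.1"),
    fish_probes("RP11-317O24", "locus", "5", 50768911, 50961846, "5q11.1"),
    fish_probes("RP11-101B14", "locus", "5", 57029637, 57212477, "5q11.2"),
    fish_probes("RP11-313I12", "locus", "5", 58287078, 58423150, "5q11.2"),
    fish_probes("RP11-343P21", "locus", "7", 24505360, 24515863, "7p15"),
    fish_probes("RP11-800L13", "locus", "8", 475607, 658638, "8p23.3")
  )
}

#' Expected Table-style FISH symbols for the chromosome-20 probe set
#'
#' The reference pattern of the fixture's two chromosome-20-containing
#' abnormal chromosomes across the chromosome 11/16/20 probe rows (one
#' symbol per derivative, "+" per copy-equivalent).
#'
#' @return Data frame `probe, der11, der20`.
#' @export
u937_fish_reference <- function() {
  dash <- "–"
  data.frame(
    probe = c("D11Z1", "KMT2A", "RP11-754N12", "FLI1", "MYH11",
              "RP11-500O11", "RP11-755M18", "RP11-218C14", "RP11-717H21",
              "RP11-580L12", "RP11-156D15", "RP11-384D7", "RP11-269F15",
              "D20Z1", "RP11-602P9", "RP11-802B20", "RP11-363M16",
              "RP11-702M08", "RP11-243J16", "RP11-71I02", "RP11-620H13",
              "RP11-483M19", "RP11-724J12", "RP11-49G10", "RP11-120F10",
              "RP11-541L2", "RP11-642P13", "D20S108"),
    der11 = c("+", dash, "+", "+", "+",
              dash, dash, dash, dash, dash, dash, dash, dash,
              dash, dash, dash, "(+)", "+", "+", "(+)", "(+)",
              dash, dash, dash, dash, dash, dash, dash),
    der20 = c(dash, dash, dash, dash, dash,
              "++++", "+++", "++", "+", "+", "+", "+", "+",
              "+", "+", "+", "+", "+", "+", "+", "+",
              "+", "+", "+", dash, dash, dash, dash),
    stringsAsFactors = FALSE
  )
}
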