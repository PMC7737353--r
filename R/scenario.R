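#' Specify a random rearrangement scenario
#'
#' A scenario is a reproducible random cell population (a shared ancestral
#' event history plus clone-specific events on a two-clone mixture), its
#' simulated array track, and a full truth record. The default genome is a
#' three-chromosome subset of the built-in map, keeping a scenario's track
#' around 12k probes.
#'
#' @param seed Integer seed driving every random choice.
#' @param chromosomes Chromosomes included in the scenario genome.
#' @param clone_fractions Cell fractions of the clones (ancestral clone
#'   first); must sum to 1.
#' @param n_events Number of ancestral rearrangement events.
#' @param n_subclonal Number of events private to the second clone
#'   (single-copy deletions/duplications, so their cell fraction is
#'   identifiable from segment data).
#' @param kind_weights Named sampling weights over ancestral event kinds.
#' @param density_per_mb,sigma_baf,sigma_lrr Array simulation parameters.
#' @param capture_event Construct one centromere-capture derivative
#'   (acentric fragments of one chromosome rescued by a short pericentromeric
#'   fragment of another).
#' @param wgd Start from a triploid founder (duplicate homologue "a").
#' @param event_size Log-uniform event size range (bp).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(seed = 1,
                          chromosomes = c("10", "11", "12"),
                          clone_fractions = c(0.6, 0.4),
                          n_events = 5, n_subclonal = 2,
                          kind_weights = c(deletion = 0.30,
                                           tandem_duplication = 0.25,
                                           inverted_duplication = 0.05,
                                           amplification = 0.10,
                                           unbalanced_translocation = 0.15,
                                           balanced_translocation = 0.10,
                                           chromosome_gain = 0.025,
                                           chromosome_loss = 0.025),
                          density_per_mb = 30, sigma_baf = 0.03,
                          sigma_lrr = 0.15, capture_event = FALSE,
                          wgd = FALSE, event_size = c(5e5, 5e7)) {
  stopifnot(abs(sum(clone_fractions) - 1) < 1e-9)
  structure(list(seed = seed, chromosomes = chromosomes,
                 clone_fractions = clone_fractions, n_events = n_events,
                 n_subclonal = n_subclonal, kind_weights = kind_weights,
                 density_per_mb = density_per_mb, sigma_baf = sigma_baf,
                 sigma_lrr = sigma_lrr, capture_event = capture_event,
                 wgd = wgd, event_size = event_size),
            class = "scenario_spec")
}

# draw an interval of log-uniform size avoiding the centromere
draw_interval <- function(map, chrom, size_range, max_tries = 50) {
  len <- chrom_length(map, chrom)
  cen <- centromere(map, chrom)
  for (t in seq_len(max_tries)) {
    size <- round(exp(stats::runif(1, log(size_range[1]),
                                   log(min(size_range[2], len / 3)))))
    start <- round(stats::runif(1, 1, len - size))
    end <- start + size - 1
    if (interval_overlap(start, end, cen$cen_start, cen$cen_end) == 0) {
      return(c(start, end))
    }
  }
  NULL
}

# draw an arm position (outside centromere, margin from the ends)
draw_arm_pos <- function(map, chrom, arm = NULL, margin = 3e6,
                         max_tries = 50) {
  len <- chrom_length(map, chrom)
  cen <- centromere(map, chrom)
  for (t in seq_len(max_tries)) {
    pos <- round(stats::runif(1, margin, len - margin))
    if (pos >= cen$cen_start - margin && pos <= cen$cen_end + margin) next
    side <- if (pos < cen$cen_start) "p" else "q"
    if (is.null(arm) || side == arm) return(list(pos = pos, arm = side))
  }
  NULL
}

random_event <- function(map, kt, kinds) {
  kind <- sample(names(kinds), 1, prob = kinds)
  # the constructed capture marker is part of the scenario contract and is
  # not a target for further random events
  members <- setdiff(names(kt$members), "capture_marker")
  m <- sample(members, 1)
  chrom_of <- function(nm) kt$members[[nm]]$segments$chrom[1]
  ch <- chrom_of(m)
  if (kind %in% c("deletion", "tandem_duplication", "inverted_duplication",
                  "amplification")) {
    iv <- draw_interval(map, ch, c(5e5, 5e7))
    if (is.null(iv)) return(NULL)
    args <- list(kind, member = m, chrom = ch, start = iv[1], end = iv[2])
    if (kind == "amplification") args$count <- sample(2:4, 1)
    return(do.call(rearrangement_event, args))
  }
  if (kind %in% c("balanced_translocation", "unbalanced_translocation")) {
    m2 <- sample(setdiff(members, m), 1)
    ch2 <- chrom_of(m2)
    if (ch2 == ch) return(NULL)
    arm <- sample(c("p", "q"), 1)
    p1 <- draw_arm_pos(map, ch, arm)
    p2 <- draw_arm_pos(map, ch2, arm)
    if (is.null(p1) || is.null(p2)) return(NULL)
    return(rearrangement_event(kind, member = m, chrom = ch, pos = p1$pos,
                               side = arm, member2 = m2, chrom2 = ch2,
                               pos2 = p2$pos, side2 = arm))
  }
  if (kind == "chromosome_gain") {
    return(rearrangement_event("chromosome_gain", member = m,
                               new_name = paste0(m, "+")))
  }
  rearrangement_event("chromosome_loss", member = m)
}

# construct a centromere-capture marker: acentric fragments of a host
# chromosome rescued by a short pericentromeric fragment of a donor
capture_marker_events <- function(map, kt) {
  members <- names(kt$members)
  chrom_of <- function(nm) kt$members[[nm]]$segments$chrom[1]
  host <- sample(members, 1)
  donor <- sample(members[vapply(members, chrom_of, "") != chrom_of(host)], 1)
  ch <- chrom_of(host)
  cd <- chrom_of(donor)
  len <- chrom_length(map, ch)
  cen <- centromere(map, ch)
  cend <- centromere(map, cd)
  # host keeps a p-arm head and a q-arm tail; its centromere is lost
  x <- round(stats::runif(1, 15e6, max(16e6, cen$cen_start - 5e6)))
  y <- round(stats::runif(1, cen$cen_end + 5e6, len - 15e6))
  r1 <- round(stats::runif(1, 1e6, 3e6))
  r2 <- round(stats::runif(1, 1e6, 3e6))
  frag <- c(cend$cen_start - r1, cend$cen_end + r2)
  list(events = list(
    rearrangement_event("deletion", member = host, chrom = ch,
                        start = x + 1, end = y - 1),
    rearrangement_event("segment_capture", member = host, after = 1,
                        member2 = donor, chrom2 = cd,
                        start2 = frag[1], end2 = frag[2],
                        orientation = "+", new_name = "capture_marker")),
    truth = data.frame(derivative = "capture_marker", kind = "centromere",
                       donor = cd, seg_start = frag[1], seg_end = frag[2],
                       host = ch, stringsAsFactors = FALSE))
}

#' Generate a random scenario with known truth
#'
#' Applies seeded random events through the karyotype model, simulates the
#' array track, and returns the ground truth alongside. Infeasible event
#' draws are redrawn and logged.
#'
#' @param spec A [scenario_spec()].
#' @return List of class `scenario`: `pop` (the [cell_population()]),
#'   `track`, `panel`, `genotypes`, `map`, and `truth` (event log, capture
#'   truth, redraw count).
#' @export
generate_scenario <- function(spec) {
  map <- genome_map(chromosomes = spec$chromosomes)
  with_seed(spec$seed, {
    members <- list()
    for (ch in spec$chromosomes) {
      members <- c(members, list(
        normal_chromosome(map, ch, "a", "a1", name = paste0(ch, ".a1")),
        normal_chromosome(map, ch, "b", "b1", name = paste0(ch, ".b1"))))
    }
    kt <- karyotype("ancestral", members)
    if (spec$wgd) {
      kt <- apply_event(kt, rearrangement_event(
        "whole_genome_duplication",
        members = paste0(spec$chromosomes, ".a1"),
        copy_names = paste0(spec$chromosomes, ".a2")))
    }
    event_log <- list()
    redraws <- 0L
    capture_truth <- NULL
    if (spec$capture_event) {
      cm <- capture_marker_events(map, kt)
      for (ev in cm$events) kt <- apply_event(kt, ev, map)
      event_log <- c(event_log, cm$events)
      capture_truth <- cm$truth
    }
    n_done <- 0L
    while (n_done < spec$n_events) {
      ev <- random_event(map, kt, spec$kind_weights)
      kt2 <- if (is.null(ev)) NULL else tryCatch(apply_event(kt, ev, map),
                                                 error = function(e) NULL)
      if (is.null(kt2) || count_chromosomes(kt2) == 0) {
        redraws <- redraws + 1L
        if (redraws > 100L) break
        next
      }
      kt <- kt2
      event_log <- c(event_log, list(ev))
      n_done <- n_done + 1L
    }
    kt$name <- "clone1"
    kt2 <- kt
    n_done <- 0L
    while (n_done < spec$n_subclonal) {
      ev <- random_event(map, kt2,
                         c(deletion = 0.5, tandem_duplication = 0.5))
      kt2b <- if (is.null(ev)) NULL else tryCatch(apply_event(kt2, ev, map),
                                                  error = function(e) NULL)
      if (is.null(kt2b) || count_chromosomes(kt2b) == 0) {
        redraws <- redraws + 1L
        if (redraws > 200L) break
        next
      }
      kt2 <- kt2b
      event_log <- c(event_log, list(ev))
      n_done <- n_done + 1L
    }
    kt2$name <- "clone2"
    pop <- cell_population(list(clone(kt, spec$clone_fractions[1]),
                                clone(kt2, spec$clone_fractions[2])))
    panel <- make_probe_panel(map, spec$density_per_mb,
                              seed = spec$seed + 1000L)
    genotypes <- assign_genotypes(panel, seed = spec$seed + 2000L)
    track <- simulate_array(pop, panel, genotypes,
                            sigma_baf = spec$sigma_baf,
                            sigma_lrr = spec$sigma_lrr,
                            seed = spec$seed + 3000L)
    structure(list(pop = pop, track = track, panel = panel,
                   genotypes = genotypes, map = map,
                   truth = list(events = event_log,
                                capture = capture_truth,
                                redraws = redraws, spec = spec)),
              class = "scenario")
  })
}

#' Per-probe truth dosage profile of a population
#'
#' @param pop A [cell_population()].
#' @param panel A probe panel.
#' @return Data frame `chrom, pos, dos_a, dos_b` of population-average
#'   homologue dosage at each probe.
#' @export
truth_profile <- function(pop, panel) {
  eff <- effective_clones(pop)
  a <- numeric(nrow(panel))
  b <- numeric(nrow(panel))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    for (e in eff) {
      d <- point_dosage(e$karyotype, ch, panel$pos[idx])
      a[idx] <- a[idx] + e$fraction * d$a
      b[idx] <- b[idx] + e$fraction * d$b
    }
  }
  data.frame(chrom = panel$chrom, pos = panel$pos, dos_a = a, dos_b = b)
}

#' Score segment calls against scenario truth
#'
#' Partitions each chromosome at the truth dosage changepoints; every truth
#' segment with at least `min_probes` probes is matched to the called segment
#' covering most of its probes and scored for homologue dosage (hence total
#' copy number). Truly mosaic truth segments additionally contribute a
#' mosaic-fraction error when a two-clone call was made.
#'
#' @param scn A `scenario` from [generate_scenario()].
#' @param calls A `segment_calls` object for `scn$track`.
#' @param min_probes Minimum probes for a truth segment to be scored.
#' @param dosage_tol Allowed absolute deviation per homologue.
#' @return List `n_segments`, `n_correct`, `mosaic_errors` (per mosaic
#'   segment `|f_hat - f_true|`, `NA` when no two-clone call was made).
#' @export
score_scenario <- function(scn, calls, min_probes = 20, dosage_tol = 0.3) {
  prof <- truth_profile(scn$pop, scn$panel)
  tab <- calls$table
  n_seg <- 0L
  n_ok <- 0L
  mosaic_err <- numeric(0)
  eff <- effective_clones(scn$pop)
  for (ch in unique(prof$chrom)) {
    p <- prof[prof$chrom == ch, , drop = FALSE]
    state <- paste(round(p$dos_a, 6), round(p$dos_b, 6))
    run <- c(1, which(state[-1] != state[-length(state)]) + 1)
    ends <- c(run[-1] - 1, nrow(p))
    for (k in seq_along(run)) {
      lo <- run[k]; hi <- ends[k]
      if (hi - lo + 1 < min_probes) next
      t_maj <- max(p$dos_a[lo], p$dos_b[lo])
      t_min <- min(p$dos_a[lo], p$dos_b[lo])
      if (t_maj + t_min == 0) next   # no signal to call
      # match the called segment covering most of this truth segment
      mid_pos <- p$pos[c(lo, hi)]
      cand <- tab[tab$chrom == ch & !is.na(tab$n_major), , drop = FALSE]
      if (nrow(cand) == 0) { n_seg <- n_seg + 1L; next }
      ov <- interval_overlap(cand$start, cand$end, mid_pos[1], mid_pos[2])
      ci <- which.max(ov)
      n_seg <- n_seg + 1L
      ok <- abs(cand$n_major[ci] - t_maj) <= dosage_tol &&
        abs(cand$n_minor[ci] - t_min) <= dosage_tol
      if (ok) n_ok <- n_ok + 1L
      # truth mosaic fraction: fraction of cells in the lower-total state
      tots <- vapply(eff, function(e) {
        d <- point_dosage(e$karyotype, ch, p$pos[lo])
        d$a + d$b
      }, 0)
      frs <- vapply(eff, `[[`, 0, "fraction")
      if (length(unique(round(tots))) == 2) {
        f_true <- sum(frs[tots < max(tots)])
        f_hat <- cand$mosaic_f[ci]
        mosaic_err <- c(mosaic_err,
                        if (is.na(f_hat)) NA_real_ else abs(f_hat - f_true))
      }
    }
  }
  list(n_segments = n_seg, n_correct = n_ok, mosaic_errors = mosaic_err)
}

#' Simulated U937 scenario
#'
#' The encoded U937 population with a simulated array track over selected
#' chromosomes and the FISH tables of the targeted probe panel.
#'
#' @param noise Named list overriding `sigma_baf` / `sigma_lrr` (defaults
#'   0.03 / 0.15; use 0 for noiseless tracks).
#' @param seed Integer seed.
#' @param chromosomes Chromosomes to simulate (default: the fully worked
#'   chromosomes 5, 6, 11, 16 and 20).
#' @param density_per_mb Probe density.
#' @param mode Clone-fraction mode of [u937_fixture()].
#' @return List `pop`, `track`, `panel`, `genotypes`, `map`, `fish`
#'   (Table-style FISH results for the two chromosome-20-bearing
#'   derivatives), `truth` (the fixture population itself).
#' @export
u937_scenario <- function(noise = list(), seed = 1,
                          chromosomes = c("5", "6", "11", "16", "20"),
                          density_per_mb = 30, mode = "nominal") {
  sb <- if (is.null(noise$sigma_baf)) 0.03 else noise$sigma_baf
  sl <- if (is.null(noise$sigma_lrr)) 0.15 else noise$sigma_lrr
  map <- genome_map()
  pop <- u937_fixture(mode, map)
  submap <- genome_map(chromosomes = chromosomes)
  panel <- make_probe_panel(submap, density_per_mb, seed = seed)
  genotypes <- assign_genotypes(panel, seed = seed + 1L)
  track <- simulate_array(pop, panel, genotypes, sigma_baf = sb,
                          sigma_lrr = sl, seed = seed + 2L)
  kt <- pop$clones[[1]]$karyotype
  fish <- fish_table(u937_fish_probes(), kt, map,
                     c("der(11)t(11;16;20)", "der(20)t(15;20)"))
  list(pop = pop, track = track, panel = panel, genotypes = genotypes,
       map = map, fish = fish, truth = pop)
}
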