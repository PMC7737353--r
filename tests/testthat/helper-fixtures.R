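# memoised fixture objects shared across test files
.cache <- new.env()

fixture_map <- function() {
  if (is.null(.cache$map)) .cache$map <- genome_map()
  .cache$map
}

fixture_pop <- function(mode = "nominal") {
  key <- paste0("pop_", mode)
  if (is.null(.cache[[key]])) .cache[[key]] <- u937_fixture(mode, fixture_map())
  .cache[[key]]
}

fixture_stemline <- function() fixture_pop()$clones[[1]]$karyotype

# a simple two-chromosome diploid toy karyotype
toy_karyotype <- function(map = fixture_map(), chroms = c("1", "2")) {
  members <- list()
  for (ch in chroms) {
    members <- c(members, list(
      normal_chromosome(map, ch, "a", "a1", name = paste0(ch, ".a1")),
      normal_chromosome(map, ch, "b", "b1", name = paste0(ch, ".b1"))))
  }
  karyotype("toy", members)
}

# simulated chromosome 6 track of the fixture (shared by several tests)
fixture_chr6_track <- function() {
  if (is.null(.cache$tr6)) {
    map6 <- genome_map(chromosomes = "6")
    panel <- make_probe_panel(map6, 30, seed = 11)
    .cache$tr6 <- simulate_array(fixture_pop(), panel,
                                 assign_genotypes(panel, seed = 12),
                                 seed = 13)
  }
  .cache$tr6
}
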