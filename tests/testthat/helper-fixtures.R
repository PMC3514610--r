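# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# three small, compositionally distinct genomes (400 kb) for fast unit tests
tb_unit_genomes <- function() {
  if (is.null(.fixtures$unit_genomes)) {
    .fixtures$unit_genomes <- lapply(1:3, function(i)
      make_genome(4e5, gc = c(0.38, 0.50, 0.62)[i], seed = 9000 + i))
  }
  .fixtures$unit_genomes
}

# small calibration tables on a reduced length grid (seconds, not minutes)
tb_unit_tables <- function() {
  if (is.null(.fixtures$unit_tables)) {
    .fixtures$unit_tables <- build_tables(
      tb_unit_genomes(),
      lengths = c(500, 1000, 2000, 5000, 10000, 20000, 50000),
      n_per_length = 50L, seed = 777)
  }
  .fixtures$unit_tables
}

# a tiny contig community with truth labels for binning tests
tb_unit_community <- function() {
  if (is.null(.fixtures$unit_comm)) {
    .fixtures$unit_comm <- make_community(
      n_genomes = 3L, genome_length = 4e5, contigs_per_genome = 40L,
      contig_length_range = c(2000, 30000), seed = 4242)
  }
  .fixtures$unit_comm
}

# random ACGT string helper
tb_random_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}
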