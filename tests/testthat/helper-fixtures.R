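# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact AA'BB genome for unit tests (full-size genomes are exercised in
# the acceptance suite)
small_genome_spec <- function(seed = 11L, ...) {
  genome_spec(chromosomes_per_subgenome = 2L, chromosome_length = 3e5,
              centromere_span = 6e4, repeat_monomer_length = 100L,
              monomers_per_family = 200L, scattered_copies = 15L,
              background_repeat_fraction = 0.02,
              gene_count_per_chromosome = 40L, gene_length = 600L,
              seed = seed, ...)
}

small_genome <- function() cached("small_genome", function()
  build_genome(small_genome_spec()))

small_kmer_matrix <- function() cached("small_kmer_matrix", function()
  count_kmers(small_genome()$sequences, k = 25, min_count = 10))

homoeolog_map_of <- function(genome) {
  chroms <- names(genome$sequences)
  stats::setNames(sub("^chr([0-9]+).*$", "set\\1", chroms), chroms)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# clock test tree: true node ages 2, 10, 30, 95; counts are exact integers
# so the clock solution is the exact optimum of the dating objective
clock_tree <- function(rate = 0.002) {
  tr <- ape::read.tree(
    text = "((((A_1:2,B_1:2):8,C_1:10):20,D_1:30):65,E_1:95);")
  tr$edge.length <- tr$edge.length * rate
  tr
}

clock_calibration <- function() {
  calibration_set(list(c("A_1", "B_1", "C_1", "D_1", "E_1")), "fixed", 95)
}

# random gene-model intervals for QC fixtures
random_models <- function(n, prefix, chroms = c("c1", "c2")) {
  start <- sample(0:5000, n, replace = TRUE)
  data.frame(model_id = paste0(prefix, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample(100:800, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
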