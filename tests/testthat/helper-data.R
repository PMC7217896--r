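# Shared synthetic fixtures, generated once per test session.

.test_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 101) {
  synthetic_config(n_chromosomes = 3, chromosome_length = 3e5,
                   n_family_genes = 18, n_decoy_genes = 40,
                   tandem_array_sizes = c(2, 5), seed = seed)
}

get_small_dataset <- function() {
  if (is.null(.test_cache$ds)) {
    .test_cache$ds <- generate_dataset(
      small_config(), file.path(tempdir(), "hspminer_test_ds"))
  }
  .test_cache$ds
}

get_full_validation <- function() {
  if (is.null(.test_cache$full)) {
    .test_cache$full <- simulate_and_validate(
      synthetic_config(seed = 2024),
      file.path(tempdir(), "hspminer_test_full"))
  }
  .test_cache$full
}

get_small_validation <- function() {
  if (is.null(.test_cache$val)) {
    .test_cache$val <- simulate_and_validate(
      small_config(), file.path(tempdir(), "hspminer_test_val"))
  }
  .test_cache$val
}

# hand-built gene models: genes at given starts with single exons
toy_models <- function(chroms, starts, strands = "+", len = 300) {
  n <- length(starts)
  strands <- rep(strands, length.out = n)
  genes <- data.frame(
    gene_id = sprintf("t%02d", seq_len(n)), chromosome = chroms,
    start = starts, end = starts + len - 1L, strand = strands,
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  gene_models(genes, exons)
}
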