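# Synthetic-genome generator: determinism, mutation model, truth
# consistency, degenerate configurations.

test_that("same seed regenerates a byte-identical bundle", {
  cfg <- synthetic_config(n_chromosomes = 2, chromosome_length = 1.5e5,
                          n_family_genes = 8, n_decoy_genes = 16,
                          tandem_array_sizes = c(2), seed = 11)
  d1 <- generate_dataset(cfg, tempfile())
  d2 <- generate_dataset(cfg, tempfile())
  for (p in names(d1$paths)) {
    expect_identical(unname(tools::md5sum(d1$paths[[p]])),
                     unname(tools::md5sum(d2$paths[[p]])), info = p)
  }
})

test_that("mutate_sequence respects rate boundaries and the binomial law", {
  s <- rand_seq(200)
  expect_identical(mutate_sequence(s, 0), s)
  m1 <- mutate_sequence(s, 1)
  expect_equal(nchar(m1), nchar(s))
  expect_false(any(strsplit(m1, "")[[1]] == strsplit(s, "")[[1]]))
  expect_identical(mutate_sequence("", 0.5), "")

  long <- rand_seq(10000)
  mut <- mutate_sequence(long, 0.3, seed = 5)
  frac <- mean(strsplit(mut, "")[[1]] != strsplit(long, "")[[1]])
  sd3 <- 3 * sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(frac - 0.3), sd3)

  # a private seed leaves the caller's RNG stream untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(mutate_sequence(long, 0.1, seed = 7))
  expect_identical(runif(1), before)
})

test_that("pseudogene_fraction = 0 yields no silent rows", {
  cfg <- synthetic_config(n_chromosomes = 2, chromosome_length = 1.5e5,
                          n_family_genes = 8, n_decoy_genes = 10,
                          tandem_array_sizes = integer(),
                          pseudogene_fraction = 0, seed = 12)
  ds <- generate_dataset(cfg, tempfile())
  expect_false(any(ds$truth$genes$is_pseudogene))
  fam <- ds$truth$genes$gene_id[ds$truth$genes$is_family_member]
  expect_true(all(rowSums(ds$tpm[fam, , drop = FALSE]) >= 1))
})

test_that("truth table, GFF3 and FASTA agree on the gene universe", {
  ds <- get_small_dataset()
  ids <- sort(ds$truth$genes$gene_id)
  expect_identical(sort(names(read_fasta(ds$paths[["proteome"]], "aa"))),
                   ids)
  expect_identical(sort(names(read_fasta(ds$paths[["cds"]], "nt"))), ids)
  expect_identical(sort(read_gff3(ds$paths[["gff"]])$genes$gene_id), ids)
  expect_false(anyDuplicated(ds$truth$genes$gene_id) > 0)
})

test_that("planted tandem arrays satisfy the layout invariants", {
  ds <- get_small_dataset()
  tg <- ds$truth$genes
  for (aid in unique(na.omit(tg$tandem_array_id))) {
    mem <- tg[!is.na(tg$tandem_array_id) & tg$tandem_array_id == aid, ]
    expect_equal(length(unique(mem$chromosome)), 1, info = aid)
    expect_equal(length(unique(mem$strand)), 1, info = aid)
    mem <- mem[order(mem$start), ]
    # consecutive members separated by at most 4 intervening genes
    for (k in seq_len(nrow(mem) - 1)) {
      between <- sum(tg$chromosome == mem$chromosome[1] &
                       tg$start > mem$end[k] & tg$end < mem$start[k + 1])
      expect_lt(between, 5)
    }
  }
})

test_that("zero planted divergence reproduces the exact consensus score", {
  cfg <- synthetic_config(n_chromosomes = 1, chromosome_length = 1e5,
                          n_family_genes = 3, n_decoy_genes = 4,
                          subfamily_mix = c(SHSP = 1),
                          tandem_array_sizes = integer(),
                          domain_divergence = 0, seed = 21)
  ds <- generate_dataset(cfg, tempfile())
  prof <- domain_profiles()[["pfam00011"]]
  fam <- ds$truth$genes$gene_id[ds$truth$genes$is_family_member]
  for (g in fam) {
    hit <- scan_profile(ds$proteome[[g]], prof, protein_id = g)
    expect_equal(nrow(hit), 1)
    expect_equal(hit$raw_score, profile_max_score(prof))
    # the gapped scan can do no better than the exhaustive ungapped oracle
    # when the planted copy is exact
    expect_equal(hit$raw_score,
                 oracle_profile_ungapped(prof$scores, ds$proteome[[g]]))
  }
})

test_that("invalid configurations and impossible layouts fail cleanly", {
  expect_error(synthetic_config(subfamily_mix = c(SHSP = 0.5, HSP40 = 0.4)),
               "summing to 1")
  expect_error(synthetic_config(tandem_array_sizes = c(2, 8)), "2..7")
  expect_error(synthetic_config(domain_divergence = 0.7))

  cfg <- synthetic_config(n_chromosomes = 1, chromosome_length = 10000,
                          n_family_genes = 6, n_decoy_genes = 10,
                          subfamily_mix = c(HSP100 = 1),
                          tandem_array_sizes = integer(), seed = 2)
  dir <- tempfile()
  expect_error(generate_dataset(cfg, dir), "layout impossible")
  expect_false(dir.exists(dir))  # no partial files
})
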