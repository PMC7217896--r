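# Profile construction, local alignment against independent oracles, and
# Karlin-Altschul score statistics.

test_that("PSSM scores follow the log-odds formula with half-bit rounding", {
  # invariant column of A, uniform background, zero pseudocount:
  # log2(1 / 0.05) = log2(20) bits, rounded to 4.5 bits = 9 half-bits;
  # unobserved residues capped at the floor
  p <- build_pssm(c("AAA", "AAA"), pseudocount_weight = 0)
  expect_true(all(p$scores[, "A"] == 2 * round(2 * log2(20)) / 2))
  expect_true(all(p$scores[, "C"] == -20))

  # observed frequencies equal to background give all-zero scores
  rows <- vapply(AA20, function(a) paste(rep(a, 3), collapse = ""),
                 character(1))
  p0 <- build_pssm(rows, pseudocount_weight = 0)
  expect_true(all(p0$scores == 0))

  # pseudocounts shrink scores toward zero (allowing half-bit rounding)
  set.seed(41)
  aln <- vapply(1:6, function(i) rand_seq(30), character(1))
  s_small <- build_pssm(aln, pseudocount_weight = 0.5)$scores
  s_large <- build_pssm(aln, pseudocount_weight = 4)$scores
  expect_true(all(abs(s_large) <= abs(s_small) + 1))
  expect_lt(mean(abs(s_large)), mean(abs(s_small)))

  expect_error(build_pssm(c("", "")), "zero")
  # all-gap columns are removed
  pg <- build_pssm(c("A-A", "A-A"))
  expect_equal(pg$length, 2)
})

test_that("Smith-Waterman equals the full-DP oracle and Biostrings", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(42)
  for (i in 1:30) {
    a <- rand_seq(sample(5:60, 1))
    b <- rand_seq(sample(5:60, 1))
    mine <- smith_waterman(a, b)$raw_score
    expect_equal(mine, oracle_sw_score(a, b, BLOSUM62, 11, 1))
    bs <- Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 11,
      gapExtension = 1, type = "local"))
    expect_equal(mine, bs)
    # symmetric matrix -> symmetric score
    expect_equal(mine, smith_waterman(b, a)$raw_score)
  }
})

test_that("Smith-Waterman handles self-alignment and degenerate input", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  s <- "MKTAYIAKQR"
  r <- smith_waterman(s, s)
  diag_sum <- sum(vapply(strsplit(s, "")[[1]],
                         function(a) BLOSUM62[a, a], numeric(1)))
  expect_equal(r$raw_score, diag_sum)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$aligned_cols, nchar(s))

  # no positive-scoring pair -> empty alignment with score 0
  r0 <- smith_waterman("AAAA", "WWWW")
  expect_equal(r0$raw_score, 0)
  expect_equal(r0$aligned_cols, 0)

  re <- smith_waterman("", "ACDE")
  expect_equal(re$raw_score, 0)
  expect_true(is.na(re$identity_pct))
  expect_true(isTRUE(attr(re, "empty_input")))
})

test_that("ungapped lambda matches the bisection oracle and closed forms", {
  m <- matrix(-1, 4, 4, dimnames = list(NT4, NT4)); diag(m) <- 1
  bg <- setNames(rep(0.25, 4), NT4)
  st <- calibrate_statistics(m, bg)
  # +1/-1 uniform 4-letter: exp(lambda) solves x/4 + 3/(4x) = 1 -> x = 3
  expect_equal(st$lambda, log(3), tolerance = 1e-6)
  expect_equal(st$lambda, oracle_lambda(c(-1, 1), c(0.75, 0.25)),
               tolerance = 1e-6)
  expect_gt(st$K, 0)

  # scaling the matrix by c scales lambda by 1/c
  st2 <- calibrate_statistics(2 * m, bg)
  expect_equal(st2$lambda, st$lambda / 2, tolerance = 1e-6)

  expect_error(calibrate_statistics(abs(m), bg), "all-positive")
  m2 <- m; diag(m2) <- 5  # expected score 0.5 >= 0
  expect_error(calibrate_statistics(m2, bg), "negative")
})

test_that("E-values are monotone in score and linear in search space", {
  st <- alignment_stats(0.267, 0.041, search_space = 1e4)
  short <- smith_waterman("MKTAYIAK", "MKTAYIAK", stats = st)
  long <- smith_waterman("MKTAYIAKQRQISFVK", "MKTAYIAKQRQISFVK", stats = st)
  expect_gt(long$raw_score, short$raw_score)
  expect_lt(long$e_value, short$e_value)

  st2 <- alignment_stats(0.267, 0.041, search_space = 2e4)
  doubled <- smith_waterman("MKTAYIAK", "MKTAYIAK", stats = st2)
  expect_equal(doubled$e_value / short$e_value, 2)
  expect_equal(doubled$bit_score, short$bit_score)  # bits ignore space
})

test_that("profile scan finds planted consensus at the exhaustive optimum", {
  profs <- domain_profiles()
  prof <- profs[["pfam00012"]]
  cons <- hsp_seed_proteins()[["pfam00012"]]
  set.seed(43)
  protein <- paste0(rand_seq(50), cons, rand_seq(60))
  hits <- scan_profile(protein, prof, protein_id = "p1")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$raw_score, profile_max_score(prof))
  expect_equal(hits$raw_score,
               oracle_profile_ungapped(prof$scores, protein))
  expect_lte(hits$query_start, 51)
  expect_gte(hits$query_end, 50 + nchar(cons))
  expect_lt(hits$e_value, 1e-4)

  # a scrambled consensus (same composition) never reaches the planted score
  shuffles <- vapply(1:50, function(i)
    paste(sample(strsplit(cons, "")[[1]]), collapse = ""), character(1))
  sc <- vapply(shuffles, function(s) {
    h <- scan_profile(paste0(rand_seq(50), s, rand_seq(60)), prof,
                      e_max = Inf, max_hits = 1)
    if (nrow(h)) h$raw_score else 0
  }, numeric(1))
  expect_true(all(sc < hits$raw_score))

  expect_equal(nrow(scan_profile("", prof)), 0)
  expect_equal(nrow(scan_profile("MKT", prof)), 0)  # < 5 residues
})

test_that("homology filtering applies the strict bit-score rule", {
  hits <- data.frame(query_id = "q", subject_id = c("a", "b", "c"),
                     e_value = c(1e-5, 1e-5, 1e-3),
                     bit_score = c(100.0, 250, 250))
  kept <- filter_homology_hits(hits, e_max = 1e-4, bit_min = 100)
  expect_identical(kept$subject_id, "b")  # bit exactly 100 rejected
  expect_equal(nrow(filter_homology_hits(hits[0, ])), 0)
})

test_that("PSSM TSV round-trip preserves the profile", {
  p <- domain_profiles()[["pfam00011"]]
  f <- tempfile()
  write_pssm(p, f)
  back <- read_pssm(f)
  expect_equal(back$scores, p$scores)
  expect_identical(back$domain_id, p$domain_id)
})
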