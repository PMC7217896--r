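# Search core: PSSM profiles, profile-sequence and sequence-sequence local
# alignment (affine gaps, Gotoh recurrences in C++), and Karlin-Altschul
# score statistics. Scores for protein work are kept in half-bit units
# (the BLOSUM62 scale), so the standard gapped constants apply directly.

#' Karlin-Altschul score statistics
#'
#' @param lambda scale parameter (nats per raw-score unit), > 0.
#' @param K Karlin-Altschul constant, > 0.
#' @param search_space optional m x n residue-pair count; when NULL,
#'   consumers default to the product of the two sequence lengths.
#' @return A `score_statistics` object.
#' @export
alignment_stats <- function(lambda, K, search_space = NULL) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K, search_space = search_space),
            class = "score_statistics")
}

# default gapped statistics per alphabet
default_stats <- function(alphabet) {
  ka <- KA_GAPPED[[ALIGN_DEFAULTS[[alphabet]]$ka]]
  alignment_stats(ka$lambda, ka$K)
}

evalue_of <- function(raw, stats, m, n) {
  space <- stats$search_space %||% (as.numeric(m) * as.numeric(n))
  stats$K * space * exp(-stats$lambda * raw)
}

bitscore_of <- function(raw, stats) {
  (stats$lambda * raw - log(stats$K)) / log(2)
}

#' Build a position-specific scoring matrix from an alignment
#'
#' Per column, residue frequencies are estimated with background-proportional
#' pseudocounts, `f_a = (n_a + w * bg_a) / (n + w)`, and converted to
#' log-odds `log2(f_a / bg_a)` in bits, rounded to the nearest half bit and
#' stored in half-bit units. All-gap columns are removed. With zero
#' pseudocount weight, unobserved residues get the floor score.
#'
#' @param aligned character vector of equal-length aligned sequences
#'   (gap = "-"), at least 2 rows.
#' @param background named residue frequency vector (sums to 1); default
#'   uniform over the 20 residues.
#' @param pseudocount_weight total pseudocount weight `w` (default 1).
#' @param domain_id label for the profile.
#' @param gap_open,gap_extend affine gap penalties in half-bit units
#'   (defaults 11 / 1, the BLOSUM62-standard pairing).
#' @param score_floor floor for minus-infinity log odds, in bits
#'   (default -10).
#' @return A `pssm_profile`: list with `domain_id`, `length`, `scores`
#'   (positions x 20, half-bit units), `background`, `gap_open`,
#'   `gap_extend`.
#' @export
build_pssm <- function(aligned, background = NULL, pseudocount_weight = 1,
                       domain_id = "domain", gap_open = 11, gap_extend = 1,
                       score_floor = -10) {
  stopifnot(length(aligned) >= 2)
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1)
    stop("alignment rows must have equal length", call. = FALSE)
  if (widths[1] == 0) stop("alignment has zero columns", call. = FALSE)
  background <- background %||%
    stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  stopifnot(abs(sum(background) - 1) < 1e-6,
            all(AA_ALPHABET %in% names(background)))
  background <- background[AA_ALPHABET]

  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  keep <- colSums(mat != "-") > 0
  mat <- mat[, keep, drop = FALSE]
  if (ncol(mat) == 0) stop("alignment has zero non-gap columns", call. = FALSE)

  scores <- matrix(0, nrow = ncol(mat), ncol = 20,
                   dimnames = list(NULL, AA_ALPHABET))
  for (p in seq_len(ncol(mat))) {
    col <- mat[, p]
    col <- col[col != "-"]
    n <- length(col)
    cnt <- table(factor(col, levels = AA_ALPHABET))
    freq <- (as.numeric(cnt) + pseudocount_weight * background) /
      (n + pseudocount_weight)
    bits <- ifelse(freq > 0, log2(freq / background), -Inf)
    bits <- pmax(bits, score_floor)
    scores[p, ] <- 2 * (round(bits * 2) / 2)  # half-bit units
  }
  structure(list(domain_id = domain_id, length = nrow(scores),
                 scores = scores, background = background,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "pssm_profile")
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat(sprintf("pssm_profile '%s': %d positions (half-bit units)\n",
              x$domain_id, x$length))
  invisible(x)
}

#' Maximum attainable ungapped profile score
#'
#' Sum over positions of the best residue score; the score an exact
#' consensus copy achieves.
#'
#' @param profile a `pssm_profile`.
#' @return Numeric scalar (half-bit units).
#' @export
profile_max_score <- function(profile) sum(apply(profile$scores, 1, max))

#' Majority-rule consensus of an alignment
#'
#' Per column the most frequent non-gap residue (ties broken alphabetically);
#' all-gap columns are dropped.
#'
#' @param aligned character vector of equal-length aligned sequences.
#' @return Single consensus string.
#' @export
consensus_sequence <- function(aligned) {
  mat <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  cons <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (!length(col)) return(NA_character_)
    tab <- table(col)
    names(tab)[order(-tab, names(tab))][1]
  })
  paste(cons[!is.na(cons)], collapse = "")
}

encode_seq <- function(seq, alphabet) {
  levels <- if (alphabet == "aa") AA_ALPHABET else NT_ALPHABET
  idx <- match(seq_chars(seq), levels)
  idx[is.na(idx)] <- 0L
  as.integer(idx - 1L)
}

#' Scan a protein with a PSSM profile
#'
#' Gapped local profile-sequence alignment; hits are reported greedily by
#' descending score with non-overlapping query spans (overlap defined on
#' protein coordinates). E-values follow `E = K * m * n * exp(-lambda * S)`.
#'
#' @param protein single amino-acid string (named, or pass `protein_id`).
#' @param profile a `pssm_profile`.
#' @param stats a `score_statistics`; default: gapped BLOSUM62-standard
#'   constants (profile scores are half-bit units).
#' @param e_max report hits with e_value <= e_max (default 1e-4).
#' @param max_hits cap on reported hits per protein/profile (default 10).
#' @param protein_id id used in the output.
#' @param search_space override the m x n search space for E-values.
#' @return Data frame of domain hits: protein_id, domain_id, query_start,
#'   query_end, raw_score, bit_score, e_value. Proteins shorter than 5
#'   residues yield an empty table.
#' @export
scan_profile <- function(protein, profile, stats = NULL, e_max = 1e-4,
                         max_hits = 10, protein_id = NULL,
                         search_space = NULL) {
  protein_id <- protein_id %||% names(protein) %||% "query"
  protein <- unname(protein)
  stats <- stats %||% default_stats("aa")
  empty <- data.frame(protein_id = character(), domain_id = character(),
                      query_start = integer(), query_end = integer(),
                      raw_score = numeric(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE)
  if (is.na(protein) || nchar(protein) < 5) return(empty)
  enc <- encode_seq(protein, "aa")
  m <- nchar(protein)
  space <- search_space %||% (as.numeric(m) * profile$length)
  mask <- rep(FALSE, m)
  hits <- list()
  for (k in seq_len(max_hits)) {
    h <- profile_scan_cpp(profile$scores, enc, profile$gap_open,
                          profile$gap_extend, mask)
    if (h$score <= 0) break
    e <- stats$K * space * exp(-stats$lambda * h$score)
    if (e > e_max) break
    hits[[k]] <- data.frame(
      protein_id = protein_id, domain_id = profile$domain_id,
      query_start = h$q_start, query_end = h$q_end,
      raw_score = h$score, bit_score = bitscore_of(h$score, stats),
      e_value = e, stringsAsFactors = FALSE)
    mask[h$q_start:h$q_end] <- TRUE
    if (all(mask)) break
  }
  if (!length(hits)) return(empty)
  do.call(rbind, hits)
}

#' Scan a whole proteome against a profile database
#'
#' E-value search space per protein is its length times the summed profile
#' length of the database (no length adjustment).
#'
#' @param proteome named character vector of protein sequences.
#' @param profiles list of `pssm_profile` objects.
#' @param e_max e-value cut-off (default 1e-4).
#' @param stats optional `score_statistics` override.
#' @return Combined domain-hit data frame.
#' @export
scan_proteome <- function(proteome, profiles, e_max = 1e-4, stats = NULL) {
  db_len <- sum(vapply(profiles, function(p) p$length, numeric(1)))
  out <- vector("list", length(proteome) * length(profiles))
  k <- 0L
  for (i in seq_along(proteome)) {
    for (prof in profiles) {
      k <- k + 1L
      out[[k]] <- scan_profile(proteome[[i]], prof, stats = stats,
                               e_max = e_max,
                               protein_id = names(proteome)[i],
                               search_space = nchar(proteome[[i]]) * db_len)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Optimal local alignment of two sequences (Smith-Waterman, affine gaps)
#'
#' Exact Gotoh dynamic programming; a gap of length k costs
#' `gap_open + k * gap_extend`. Percent identity is computed from the
#' traceback with alignment columns (including gap columns) as the
#' denominator.
#'
#' @param a,b sequences (single strings; names become query/subject ids).
#' @param matrix substitution matrix; default BLOSUM62 for `alphabet="aa"`,
#'   +1/-2 for `"nt"`.
#' @param gap_open,gap_extend penalties (defaults 11/1 for aa, 5/2 for nt).
#' @param alphabet `"aa"` or `"nt"`.
#' @param stats `score_statistics` for bit score / E-value; defaults to the
#'   standard gapped constants for the scoring system.
#' @param query_id,subject_id ids for the output row.
#' @return One-row data frame: query_id, subject_id, raw_score, bit_score,
#'   e_value, identity_pct, aligned_cols, query_start/end,
#'   subject_start/end. An empty input yields raw_score 0 with
#'   identity_pct NA (flagged, not an error).
#' @export
smith_waterman <- function(a, b, matrix = NULL, gap_open = NULL,
                           gap_extend = NULL, alphabet = c("aa", "nt"),
                           stats = NULL, query_id = NULL, subject_id = NULL) {
  alphabet <- match.arg(alphabet)
  query_id <- query_id %||% names(a) %||% "query"
  subject_id <- subject_id %||% names(b) %||% "subject"
  a <- unname(a); b <- unname(b)
  defs <- ALIGN_DEFAULTS[[alphabet]]
  gap_open <- gap_open %||% defs$gap_open
  gap_extend <- gap_extend %||% defs$gap_extend
  matrix <- matrix %||%
    (if (alphabet == "aa") blosum62_matrix() else nucleotide_matrix())
  stats <- stats %||% default_stats(alphabet)

  levels <- rownames(matrix)
  enc <- function(s) {
    idx <- match(seq_chars(s), levels)
    idx[is.na(idx)] <- 0L
    as.integer(idx - 1L)
  }
  if (nchar(a) == 0 || nchar(b) == 0) {
    out <- data.frame(query_id = query_id, subject_id = subject_id,
                      raw_score = 0, bit_score = NA_real_,
                      e_value = NA_real_, identity_pct = NA_real_,
                      aligned_cols = 0L, query_start = 0L, query_end = 0L,
                      subject_start = 0L, subject_end = 0L,
                      stringsAsFactors = FALSE)
    attr(out, "empty_input") <- TRUE
    return(out)
  }
  r <- sw_align_cpp(enc(a), enc(b), matrix, gap_open, gap_extend)
  data.frame(
    query_id = query_id, subject_id = subject_id, raw_score = r$score,
    bit_score = bitscore_of(r$score, stats),
    e_value = evalue_of(r$score, stats, nchar(a), nchar(b)),
    identity_pct = if (r$aligned_cols > 0) 100 * r$identical / r$aligned_cols
                   else NA_real_,
    aligned_cols = r$aligned_cols,
    query_start = r$a_start, query_end = r$a_end,
    subject_start = r$b_start, subject_end = r$b_end,
    stringsAsFactors = FALSE)
}

#' Homology search of seed proteins against a proteome
#'
#' Aligns every seed against every target (Smith-Waterman); E-values use a
#' database-level search space, seed length times summed proteome length.
#'
#' @param proteome named character vector of targets.
#' @param seeds named character vector of query (known-family) proteins.
#' @param ... passed to [smith_waterman()].
#' @return Data frame of alignment results (one row per seed x target with
#'   positive score); filter with [filter_homology_hits()].
#' @export
homology_search <- function(proteome, seeds, ...) {
  db_len <- sum(nchar(proteome))
  out <- list()
  k <- 0L
  for (s in seq_along(seeds)) {
    stats <- alignment_stats(default_stats("aa")$lambda,
                             default_stats("aa")$K,
                             search_space = nchar(seeds[[s]]) * db_len)
    for (t in seq_along(proteome)) {
      r <- smith_waterman(seeds[[s]], proteome[[t]], stats = stats,
                          query_id = names(seeds)[s],
                          subject_id = names(proteome)[t], ...)
      if (r$raw_score > 0) { k <- k + 1L; out[[k]] <- r }
    }
  }
  res <- do.call(rbind, out) %||% smith_waterman("A", "A")[0, ]
  rownames(res) <- NULL
  res
}

#' Filter homology hits by E-value and bit score
#'
#' Keeps hits with `e_value <= e_max` and `bit_score > bit_min`; the bit
#' score comparison is strict.
#'
#' @param hits alignment-result data frame.
#' @param e_max e-value ceiling (default 1e-4).
#' @param bit_min strict bit-score floor (default 100).
#' @return Filtered data frame.
#' @export
filter_homology_hits <- function(hits, e_max = 1e-4, bit_min = 100) {
  stopifnot(all(c("e_value", "bit_score") %in% names(hits)))
  hits[!is.na(hits$e_value) & hits$e_value <= e_max &
         hits$bit_score > bit_min, , drop = FALSE]
}

#' Calibrate Karlin-Altschul statistics for a scoring system
#'
#' Ungapped mode solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for
#' `lambda > 0` by bracketed root finding and computes K by the standard
#' lattice series approximation. Gapped scoring has no analytic theory, so
#' `mode = "gapped"` returns the supplied (or preset) calibrated constants.
#'
#' @param matrix substitution matrix with row/column names.
#' @param background named residue frequencies for the rows (and columns,
#'   unless `background2` given).
#' @param background2 optional column-side frequencies.
#' @param mode `"ungapped"` (compute) or `"gapped"` (configured constants).
#' @param gapped_constants list with `lambda` and `K`, or the name of a
#'   bundled preset (`"blosum62_11_1"`, `"nuc_1_2_5_2"`).
#' @param k_terms number of terms in the K series (default 60).
#' @return A `score_statistics` object.
#' @export
calibrate_statistics <- function(matrix, background, background2 = background,
                                 mode = c("ungapped", "gapped"),
                                 gapped_constants = "blosum62_11_1",
                                 k_terms = 60) {
  mode <- match.arg(mode)
  if (mode == "gapped") {
    gc <- if (is.character(gapped_constants)) KA_GAPPED[[gapped_constants]]
          else gapped_constants
    return(alignment_stats(gc$lambda, gc$K))
  }
  stopifnot(!is.null(rownames(matrix)), !is.null(colnames(matrix)))
  p1 <- background[rownames(matrix)]
  p2 <- background2[colnames(matrix)]
  stopifnot(!anyNA(p1), !anyNA(p2),
            abs(sum(p1) - 1) < 1e-6, abs(sum(p2) - 1) < 1e-6)
  pij <- outer(p1, p2)
  s <- matrix
  if (max(s) <= 0) stop("matrix has no positive score: lambda undefined",
                        call. = FALSE)
  if (min(s) >= 0) stop("all-positive matrix: no finite lambda",
                        call. = FALSE)
  esc <- sum(pij * s)
  if (esc >= 0)
    stop("expected score under background must be negative", call. = FALSE)

  # put scores on an integer lattice
  mult <- NA
  for (m in 1:64) {
    if (all(abs(s * m - round(s * m)) < 1e-9)) { mult <- m; break }
  }
  if (is.na(mult)) stop("scores are not on a rational lattice", call. = FALSE)
  si <- round(s * mult)

  # aggregated score distribution
  vals <- sort(unique(as.vector(si)))
  probs <- vapply(vals, function(v) sum(pij[si == v]), numeric(1))

  f <- function(lam) sum(probs * exp(lam * vals)) - 1
  hi <- 0.5
  while (f(hi) < 0) hi <- hi * 2
  lam <- stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root

  # relative entropy H (nats per aligned pair, lattice units)
  H <- lam * sum(probs * vals * exp(lam * vals))

  # delta = lattice period of achievable scores
  delta <- Reduce(function(a, b) {
    while (b) { t <- b; b <- a %% b; a <- t }; a
  }, abs(vals[vals != 0]))

  # sigma series over sums of k i.i.d. scores (truncated convolution)
  lo <- min(vals); hi_v <- max(vals)
  offset <- 1 - lo * k_terms
  dist <- rep(0, hi_v * k_terms + offset)
  dist[vals + offset] <- probs
  cur <- dist
  sigma <- 0
  base <- rep(0, length(dist)); base[vals + offset] <- probs
  supp <- function(v) seq_along(v) - offset
  for (k in seq_len(k_terms)) {
    if (k > 1) {
      new <- rep(0, length(dist))
      nz <- which(cur > 0)
      for (i in nz) {
        sh <- (i - offset) + vals + offset
        ok <- sh >= 1 & sh <= length(new)
        new[sh[ok]] <- new[sh[ok]] + cur[i] * probs[ok]
      }
      cur <- new
    }
    sc <- supp(cur)
    pos <- sum(cur[sc >= 0])
    negi <- which(sc < 0)
    term <- (pos + sum(cur[negi] * exp(lam * sc[negi]))) / k
    sigma <- sigma + term
    if (term < 1e-10) break
  }
  K <- delta * lam * exp(-2 * sigma) / (H * (1 - exp(-lam * delta)))
  # lambda back in the matrix's own score units
  alignment_stats(lam * mult, K)
}

#' Write a PSSM profile as TSV
#'
#' Columns: domain_id, position, then the 20 residue scores (half-bit
#' units).
#'
#' @param profile a `pssm_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path) {
  df <- data.frame(domain_id = profile$domain_id,
                   position = seq_len(profile$length),
                   profile$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_versioned(df, path)
}

#' Read a PSSM profile from TSV
#'
#' @param path file written by [write_pssm()].
#' @param gap_open,gap_extend gap penalties to attach (half-bit units).
#' @param background background frequencies (default uniform).
#' @return A `pssm_profile`.
#' @export
read_pssm <- function(path, gap_open = 11, gap_extend = 1,
                      background = NULL) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("domain_id", "position", AA_ALPHABET) %in% names(df)))
  df <- df[order(df$position), ]
  scores <- as.matrix(df[, AA_ALPHABET])
  rownames(scores) <- NULL
  structure(list(domain_id = df$domain_id[1], length = nrow(scores),
                 scores = scores,
                 background = background %||%
                   stats::setNames(rep(1 / 20, 20), AA_ALPHABET),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "pssm_profile")
}
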