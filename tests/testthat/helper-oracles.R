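# Independent oracles, written plainly and without the optimizations used
# by the implementation they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT4 <- c("A", "C", "G", "T")

rand_seq <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Full local-alignment DP with explicit gap-length scan (Waterman-Smith-
# Beyer form, no affine-state optimization). Gap of length k costs
# gap_open + k * gap_extend.
oracle_sw_score <- function(a, b, mat, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cand <- c(0, H[i, j] + mat[A[i], B[j]],
                max(H[i:1, j + 1] - gap_open - seq_len(i) * gap_extend),
                max(H[i + 1, j:1] - gap_open - seq_len(j) * gap_extend))
      H[i + 1, j + 1] <- max(cand)
    }
  }
  max(H)
}

# bisection root of sum(p * exp(lambda * s)) = 1 on lambda > 0
oracle_lambda <- function(vals, probs, tol = 1e-12) {
  f <- function(l) sum(probs * exp(l * vals)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lo <- 1e-12
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# best ungapped profile-vs-sequence score over all offsets (exhaustive)
oracle_profile_ungapped <- function(scores, seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- nrow(scores); n <- length(ch)
  if (n < L) return(-Inf)
  best <- -Inf
  for (off in 0:(n - L)) {
    s <- 0
    for (p in seq_len(L)) s <- s + scores[p, ch[off + p]]
    best <- max(best, s)
  }
  best
}

# naive position-by-position IUPAC motif counter (double loop)
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_count_motif <- function(seq, pattern, both_strands = TRUE) {
  count_one <- function(s, pat) {
    sc <- strsplit(s, "")[[1]]; pc <- strsplit(pat, "")[[1]]
    L <- length(pc); n <- length(sc)
    if (L > n) return(0L)
    total <- 0L
    for (off in 0:(n - L)) {
      hit <- TRUE
      for (k in seq_len(L)) {
        if (!(sc[off + k] %in% ORACLE_IUPAC[[pc[k]]])) { hit <- FALSE; break }
      }
      if (hit) total <- total + 1L
    }
    total
  }
  n <- count_one(seq, pattern)
  if (both_strands && oracle_revcomp(pattern) != pattern)
    n <- n + count_one(seq, oracle_revcomp(pattern))
  n
}

# independent Henderson-Hasselbalch charge + 0.001-step grid search for pI
oracle_charge <- function(seq, pH, pka) {
  ch <- strsplit(seq, "")[[1]]
  pos <- c(Nterm = 1, H = sum(ch == "H"), K = sum(ch == "K"),
           R = sum(ch == "R"))
  neg <- c(Cterm = 1, C = sum(ch == "C"), D = sum(ch == "D"),
           E = sum(ch == "E"), Y = sum(ch == "Y"))
  sum(pos / (1 + 10^(pH - pka[names(pos)]))) -
    sum(neg / (1 + 10^(pka[names(neg)] - pH)))
}

oracle_pi_grid <- function(seq, pka, step = 0.001) {
  grid <- seq(0, 14, by = step)
  charges <- vapply(grid, function(p) oracle_charge(seq, p, pka),
                    numeric(1))
  grid[which.min(abs(charges))]
}

# brute-force all-pairs tandem detector (no sortedness assumptions)
oracle_tandem_pairs <- function(family_ids, genes, proteins,
                                identity_min = 40, max_intervening = 5) {
  out <- character()
  fam <- genes[genes$gene_id %in% family_ids & genes$chromosome != "Un", ]
  if (nrow(fam) < 2) return(out)
  for (i in 1:(nrow(fam) - 1)) {
    for (j in (i + 1):nrow(fam)) {
      g1 <- fam[i, ]; g2 <- fam[j, ]
      if (g1$chromosome != g2$chromosome || g1$strand != g2$strand) next
      left <- if (g1$start <= g2$start) g1 else g2
      right <- if (g1$start <= g2$start) g2 else g1
      allg <- genes[genes$chromosome == g1$chromosome, ]
      iv <- sum(allg$start > left$end & allg$end < right$start)
      if (iv >= max_intervening) next
      aln <- smith_waterman(proteins[[left$gene_id]],
                            proteins[[right$gene_id]], alphabet = "aa")
      if (is.na(aln$identity_pct) || aln$identity_pct <= identity_min) next
      out <- c(out, paste(left$gene_id, right$gene_id))
    }
  }
  sort(out)
}
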