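# Physico-chemical characterization (molecular weight, isoelectric point)
# and promoter scanning for cis-acting regulatory elements (CAREs).

#' Average molecular weight of a peptide
#'
#' Sum of average (isotope-averaged) residue masses plus one water.
#' X contributes a configurable average mass (default: mean of the 20
#' standard residues).
#'
#' @param seq amino-acid string (non-empty).
#' @param x_mass mass contributed by X (default mean residue mass).
#' @return Molecular weight in Da.
#' @export
molecular_weight <- function(seq, x_mass = mean(AA_AVG_MASS)) {
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- seq_chars(toupper(seq))
  ch <- ch[ch != "*"]
  masses <- AA_AVG_MASS[ch]
  masses[ch == "X"] <- x_mass
  if (anyNA(masses))
    stop(sprintf("unknown residue '%s'", ch[which(is.na(masses))[1]]),
         call. = FALSE)
  sum(masses) + WATER_MASS
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch fractional charges: positive groups (N-terminus,
#' H, K, R) contribute `1 / (1 + 10^(pH - pKa))`, negative groups
#' (C-terminus, D, E, C, Y) contribute `-1 / (1 + 10^(pKa - pH))`.
#'
#' @param seq amino-acid string.
#' @param pH pH value(s).
#' @param pka_table `"ipc"` (default), `"emboss"`, or a named numeric vector
#'   with entries Nterm, Cterm, C, D, E, H, K, R, Y.
#' @param termini include the terminal groups (default TRUE).
#' @return Net charge (vectorized over `pH`).
#' @export
protein_charge <- function(seq, pH, pka_table = "ipc", termini = TRUE) {
  pka <- if (is.character(pka_table)) PKA_TABLES[[pka_table]] else pka_table
  stopifnot(!is.null(pka), all(c("Nterm", "Cterm") %in% names(pka)))
  ch <- seq_chars(toupper(seq))
  counts <- table(factor(ch, levels = c("C", "D", "E", "H", "K", "R", "Y")))
  pos_groups <- c(H = unname(counts["H"]), K = unname(counts["K"]),
                  R = unname(counts["R"]))
  neg_groups <- c(C = unname(counts["C"]), D = unname(counts["D"]),
                  E = unname(counts["E"]), Y = unname(counts["Y"]))
  if (termini) pos_groups <- c(Nterm = 1, pos_groups)
  if (termini) neg_groups <- c(Cterm = 1, neg_groups)
  if (sum(pos_groups) + sum(neg_groups) == 0)
    stop("no ionizable groups in sequence and termini excluded",
         call. = FALSE)
  vapply(pH, function(p) {
    pos <- sum(pos_groups / (1 + 10^(p - pka[names(pos_groups)])))
    neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point by bisection
#'
#' Finds the pH in [0, 14] where the net Henderson-Hasselbalch charge is
#' zero, by bisection to `|charge| < tol`. The charge curve is strictly
#' decreasing in pH, so the root is unique.
#'
#' @inheritParams protein_charge
#' @param tol charge tolerance at the returned pH (default 1e-4).
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_table = "ipc", termini = TRUE,
                              tol = 1e-4) {
  f <- function(p) protein_charge(seq, p, pka_table, termini)
  lo <- 0; hi <- 14
  flo <- f(lo); fhi <- f(hi)
  if (flo <= 0) return(lo)
  if (fhi >= 0) return(hi)
  while ((hi - lo) > 1e-8) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(f(mid)) >= tol)
    warning("charge at returned pI exceeds tolerance", call. = FALSE)
  mid
}

#' Load a CARE motif catalogue
#'
#' TSV with columns name, pattern (IUPAC nucleotide), category. Patterns
#' are validated at load time; an illegal IUPAC symbol is an error.
#'
#' @param path TSV file; default: the bundled catalogue of common plant
#'   promoter elements.
#' @return Data frame: name, pattern, category.
#' @export
read_care_motifs <- function(path = system.file("extdata",
                                                "care_motifs.tsv",
                                                package = "hspminer")) {
  df <- read_tsv_plain(path)
  stopifnot(all(c("name", "pattern", "category") %in% names(df)))
  df$pattern <- toupper(df$pattern)
  for (i in seq_len(nrow(df))) {
    if (!nchar(df$pattern[i])) stop("empty motif pattern", call. = FALSE)
    bad <- setdiff(seq_chars(df$pattern[i]), names(IUPAC_NT))
    if (length(bad))
      stop(sprintf("illegal IUPAC symbol '%s' in motif '%s'",
                   bad[1], df$name[i]), call. = FALSE)
  }
  df
}

# is an IUPAC pattern its own reverse complement (as a degenerate set)?
is_palindromic_pattern <- function(pattern) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pattern)))
  identical(rc, pattern)
}

#' Count CARE motif occurrences in a promoter
#'
#' Every (possibly overlapping) occurrence of the IUPAC-expanded pattern is
#' counted; with `both_strands = TRUE`, reverse-strand occurrences of
#' non-palindromic motifs are added, while palindromic patterns are counted
#' once per position.
#'
#' @param promoter nucleotide string (A/C/G/T).
#' @param motifs motif catalogue from [read_care_motifs()].
#' @param both_strands scan both strands (default TRUE).
#' @return Named integer vector of per-motif counts.
#' @export
scan_cares <- function(promoter, motifs, both_strands = TRUE) {
  promoter <- toupper(as.character(promoter))
  counts <- stats::setNames(integer(nrow(motifs)), motifs$name)
  if (!nchar(promoter)) return(counts)
  subject <- Biostrings::DNAString(promoter)
  for (i in seq_len(nrow(motifs))) {
    pat <- motifs$pattern[i]
    if (nchar(pat) > nchar(promoter)) next
    n <- Biostrings::countPattern(pat, subject, fixed = FALSE)
    if (both_strands && !is_palindromic_pattern(pat)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(pat)))
      n <- n + Biostrings::countPattern(rc, subject, fixed = FALSE)
    }
    counts[i] <- n
  }
  counts
}

#' Summarize CARE occurrences per sub-family
#'
#' @param per_gene_counts matrix genes x motifs of occurrence counts.
#' @param records data frame with gene_id and subfamily covering the rows.
#' @param motifs motif catalogue (for categories).
#' @param top_k how many most-frequent motifs to list per category
#'   (default 3).
#' @return List: `per_subfamily` (sub-family x motif count matrix),
#'   `unique_motif_count` per sub-family, `family_unique_count`,
#'   `top_by_category` data frame.
#' @export
summarize_cares <- function(per_gene_counts, records, motifs, top_k = 3) {
  fams <- sort(unique(records$subfamily))
  if (!length(fams)) {
    per_fam <- matrix(0, 0, nrow(motifs),
                      dimnames = list(character(), motifs$name))
    return(list(per_subfamily = per_fam,
                unique_motif_count = integer(),
                family_unique_count = 0L, top_by_category = NULL))
  }
  per_fam <- t(vapply(fams, function(fam) {
    ids <- intersect(records$gene_id[records$subfamily == fam],
                     rownames(per_gene_counts))
    colSums(per_gene_counts[ids, , drop = FALSE])
  }, numeric(ncol(per_gene_counts))))
  rownames(per_fam) <- fams
  unique_count <- apply(per_fam, 1, function(x) sum(x > 0))
  family_unique <- sum(colSums(per_fam) > 0)

  totals <- colSums(per_fam)
  top_rows <- lapply(unique(motifs$category), function(cat) {
    ms <- motifs$name[motifs$category == cat]
    ms <- ms[order(-totals[ms], ms)]
    ms <- ms[totals[ms] > 0]
    if (!length(ms)) return(NULL)
    ms <- utils::head(ms, top_k)
    data.frame(category = cat, motif = ms, total = unname(totals[ms]),
               stringsAsFactors = FALSE)
  })
  list(per_subfamily = per_fam, unique_motif_count = unique_count,
       family_unique_count = family_unique,
       top_by_category = do.call(rbind, top_rows))
}
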