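# Bundled physico-chemical tables, codon map and IUPAC expansion.

# Average (isotope-averaged) residue masses in Da; a peptide's mass is the
# sum of residue masses plus one water.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# pKa sets for the Henderson-Hasselbalch charge model. "ipc" follows the
# IPC protein-optimized set; "emboss" is the EMBOSS iep default.
PKA_TABLES <- list(
  ipc = c(Nterm = 9.094, Cterm = 2.869, C = 7.555, D = 3.872, E = 4.412,
          H = 5.637, K = 9.052, R = 11.84, Y = 10.85),
  emboss = c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
             H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
)

# One fixed codon per amino acid for reverse translation of synthetic
# proteins (realistic codon usage is out of scope for the generator).
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT"
)
STOP_CODON <- "TAA"

IUPAC_NT <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Karlin-Altschul constants for gapped search modes. Analytic theory covers
# only ungapped scoring, so gapped modes use the field-standard calibrated
# constants for the corresponding scoring system.
KA_GAPPED <- list(
  blosum62_11_1 = list(lambda = 0.267, K = 0.041),
  nuc_1_2_5_2 = list(lambda = 1.28, K = 0.46)
)

# Default alignment parameter sets per alphabet
ALIGN_DEFAULTS <- list(
  aa = list(gap_open = 11, gap_extend = 1, ka = "blosum62_11_1"),
  nt = list(gap_open = 5, gap_extend = 2, ka = "nuc_1_2_5_2")
)

# +1/-2 match/mismatch matrix for nucleotide local alignment
nucleotide_matrix <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, 4, 4, dimnames = list(NT_ALPHABET, NT_ALPHABET))
  diag(m) <- match
  m
}

# BLOSUM62 restricted to the 20 standard residues, via Biostrings' bundled
# copy (lazy to avoid loading data at build time)
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})
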