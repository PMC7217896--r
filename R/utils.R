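# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
NT_ALPHABET <- c("A", "C", "G", "T")

#' Run code with a private, seeded RNG stream
#'
#' Saves and restores the global `.Random.seed` so that seeded package
#' internals never perturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed so that independent generator stages
# do not share identical draws. Kept below 2^31.
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 48271 + offset) %% 2147483587
}

#' Reverse complement of a nucleotide string
#'
#' Complements IUPAC ambiguity symbols as well as A/C/G/T; an involution.
#'
#' @param seq single nucleotide string.
#' @return The reverse-complemented string.
#' @export
#' @examples
#' reverse_complement("ACGTN")
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# split a sequence string into single characters
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# validate residue symbols; returns invisibly, errors with 1-based position
check_alphabet <- function(seq, alphabet = c("aa", "nt"), id = "<sequence>") {
  alphabet <- match.arg(alphabet)
  legal <- if (alphabet == "aa") c(AA_ALPHABET, "X", "*") else c(NT_ALPHABET, "N")
  ch <- seq_chars(seq)
  bad <- which(!ch %in% legal)
  if (length(bad))
    stop(sprintf("illegal %s symbol '%s' at position %d in record '%s'",
                 if (alphabet == "aa") "amino-acid" else "nucleotide",
                 ch[bad[1]], bad[1], id), call. = FALSE)
  invisible(TRUE)
}

# write a data.frame as TSV with a tool-version comment header (deterministic)
write_tsv_versioned <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# hspminer %s",
                     as.character(utils::packageVersion("hspminer"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# natural sort order for wheat-style chromosome names: 1A, 1B, 1D, 2A, ...,
# with "Un" (unplaced) always last
chromosome_order <- function(chroms) {
  u <- unique(chroms)
  un <- u == "Un"
  num <- suppressWarnings(as.numeric(gsub("[^0-9]", "", u)))
  num[is.na(num)] <- Inf
  letter <- gsub("[0-9]", "", u)
  ord <- order(un, num, letter)
  u[ord]
}

#' Sub-genome label from a chromosome name
#'
#' Parses the trailing letter of a wheat-style chromosome name ("7D" -> "D").
#' Returns `NA` when no trailing sub-genome letter is present (including the
#' unplaced scaffold "Un").
#'
#' @param chromosome character vector of chromosome names.
#' @return character vector of sub-genome labels (or `NA`).
#' @export
subgenome_of <- function(chromosome) {
  out <- ifelse(grepl("^[0-9]+[A-Z]$", chromosome),
                sub("^[0-9]+", "", chromosome), NA_character_)
  out[chromosome == "Un"] <- NA_character_
  out
}
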