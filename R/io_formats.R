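# Standard-format readers and writers. All genomic coordinates are 1-based
# and inclusive throughout the package; any half-open convention is confined
# to this file's writers (none currently needed).

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read; in nucleotide mode U is mapped to T.
#' Residues are validated against the declared alphabet (plus X for proteins
#' and N for nucleotides), with the offending position reported.
#'
#' @param path FASTA file.
#' @param alphabet `"aa"` or `"nt"`.
#' @param allow_empty permit zero-length sequences (default FALSE).
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt"), allow_empty = FALSE) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id '%s' in %s", dup[1], path), call. = FALSE)
  seqs <- toupper(as.character(set))
  if (alphabet == "nt") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    if (!allow_empty && nchar(seqs[[i]]) == 0L)
      stop(sprintf("empty sequence for record '%s'", ids[i]), call. = FALSE)
    check_alphabet(seqs[[i]], alphabet, ids[i])
  }
  seqs
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, n)), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene, mRNA and exon features (via rtracklayer) into a
#' `gene_models` container. Exon lists are stored sorted ascending by start
#' regardless of strand. Per-gene exons are those of the longest annotated
#' transcript (by summed exon length); the per-transcript structure is kept
#' for isoform-aware naming.
#'
#' @param path GFF3 file.
#' @return A `gene_models` object: list with `genes`, `mrnas` and `exons`
#'   data frames.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  df <- data.frame(
    type = type,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(gr$ID),
    stringsAsFactors = FALSE
  )
  parent <- gr$Parent
  df$parent <- vapply(seq_along(parent), function(i) {
    p <- parent[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  if (any(df$end < df$start)) stop("GFF3 feature with end < start", call. = FALSE)

  genes <- df[df$type == "gene", ]
  mrnas <- df[df$type == "mRNA", ]
  exons <- df[df$type == "exon", ]
  if (nrow(exons) && anyNA(exons$parent))
    stop("exon feature without Parent attribute", call. = FALSE)
  if (!all(exons$parent %in% c(mrnas$id, genes$id)))
    stop(sprintf("exon with unknown parent '%s'",
                 setdiff(exons$parent, c(mrnas$id, genes$id))[1]), call. = FALSE)
  # map exon -> gene (directly, or through its mRNA)
  mrna_gene <- stats::setNames(mrnas$parent, mrnas$id)
  if (nrow(mrnas) && !all(mrnas$parent %in% genes$id))
    stop("mRNA feature whose Parent is not a gene", call. = FALSE)
  exon_mrna <- ifelse(exons$parent %in% mrnas$id, exons$parent, NA_character_)
  exon_gene <- ifelse(is.na(exon_mrna), exons$parent, mrna_gene[exon_mrna])

  exons_df <- data.frame(gene_id = exon_gene, mrna_id = exon_mrna,
                         start = exons$start, end = exons$end,
                         stringsAsFactors = FALSE)
  exons_df <- exons_df[order(exons_df$gene_id, exons_df$start, exons_df$end), ]

  mrnas_df <- data.frame(mrna_id = mrnas$id, gene_id = mrnas$parent,
                         start = mrnas$start, end = mrnas$end,
                         stringsAsFactors = FALSE)
  mrnas_df <- mrnas_df[order(match(mrnas_df$gene_id, genes$id)), ]

  genes_df <- data.frame(
    gene_id = genes$id, chromosome = genes$chromosome,
    start = genes$start, end = genes$end, strand = genes$strand,
    subgenome = subgenome_of(genes$chromosome),
    stringsAsFactors = FALSE
  )
  gene_models(genes_df, exons_df, mrnas_df)
}

#' Construct a gene_models container
#'
#' @param genes data frame with gene_id, chromosome, start, end, strand
#'   (subgenome derived if absent).
#' @param exons data frame with gene_id, start, end (optional mrna_id).
#' @param mrnas optional data frame with mrna_id, gene_id.
#' @return A `gene_models` object whose `exons` slot holds, per gene, the
#'   exons of the longest transcript, sorted ascending and checked
#'   non-overlapping.
#' @export
gene_models <- function(genes, exons, mrnas = NULL) {
  stopifnot(all(c("gene_id", "chromosome", "start", "end", "strand") %in%
                  names(genes)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in gene set", call. = FALSE)
  if (any(genes$end < genes$start)) stop("gene with end < start", call. = FALSE)
  if (is.null(genes$subgenome)) genes$subgenome <- subgenome_of(genes$chromosome)
  if (is.null(exons$mrna_id)) exons$mrna_id <- NA_character_

  # representative transcript per gene = longest by summed exon length
  if (!nrow(genes)) {
    empty_ex <- data.frame(gene_id = character(), mrna_id = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
    return(structure(list(genes = genes, exons = empty_ex,
                          all_exons = empty_ex, mrnas = mrnas),
                     class = "gene_models"))
  }
  rep_exons <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    if (all(is.na(e$mrna_id)) || length(unique(stats::na.omit(e$mrna_id))) <= 1)
      return(e)
    len <- tapply(e$end - e$start + 1, e$mrna_id, sum)
    keep <- names(len)[order(-len, names(len))][1]
    e[!is.na(e$mrna_id) & e$mrna_id == keep, ]
  }))
  rep_exons <- rep_exons[order(rep_exons$gene_id, rep_exons$start), ]
  rownames(rep_exons) <- NULL
  for (g in unique(rep_exons$gene_id)) {
    e <- rep_exons[rep_exons$gene_id == g, ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop(sprintf("overlapping exons in gene '%s'", g), call. = FALSE)
    gi <- match(g, genes$gene_id)
    if (!is.na(gi) && (min(e$start) < genes$start[gi] ||
                       max(e$end) > genes$end[gi]))
      stop(sprintf("exon outside gene span in '%s'", g), call. = FALSE)
  }
  structure(list(genes = genes, exons = rep_exons, all_exons = exons,
                 mrnas = mrnas), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes on %d sequence(s)\n",
              nrow(x$genes), length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS features with ID/Parent attributes, a
#' `##gff-version 3` pragma and a tool-version comment line. Deterministic
#' output (no timestamps), so reruns are byte-identical.
#'
#' @param models a `gene_models` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("# hspminer %s",
                     as.character(utils::packageVersion("hspminer"))), con)
  g <- models$genes
  ex <- models$exons
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(sprintf("%s\thspminer\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chromosome[i], g$start[i], g$end[i], g$strand[i], gid),
               con)
    mid <- paste0(gid, ".1")
    writeLines(sprintf("%s\thspminer\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chromosome[i], g$start[i], g$end[i], g$strand[i],
                       mid, gid), con)
    e <- ex[ex$gene_id == gid, , drop = FALSE]
    for (k in seq_len(nrow(e))) {
      for (ft in c("exon", "CDS")) {
        writeLines(sprintf(
          "%s\thspminer\t%s\t%d\t%d\t.\t%s\t%s\tID=%s:%s%d;Parent=%s",
          g$chromosome[i], ft, e$start[k], e$end[k], g$strand[i],
          if (ft == "CDS") "0" else ".", mid, ft, k, mid), con)
      }
    }
  }
  invisible(path)
}

#' Extract the promoter (upstream region) of a gene
#'
#' Plus strand: bases `[start - length, start - 1]`; minus strand: the
#' reverse complement of `[end + 1, end + length]`. Clipped at chromosome
#' boundaries, so the returned sequence may be shorter than `length`; a gene
#' flush against the boundary yields a zero-length promoter with attribute
#' `clipped = TRUE` rather than an error.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gene one-row data frame (or list) with chromosome, start, end,
#'   strand.
#' @param length promoter length in bp (default 1500).
#' @return Single promoter string with attributes `gene_id` (if present) and
#'   `clipped`.
#' @export
extract_promoter <- function(genome, gene, length = 1500) {
  chrom <- gene$chromosome
  if (!chrom %in% names(genome))
    stop(sprintf("chromosome '%s' not in genome", chrom), call. = FALSE)
  chrom_seq <- genome[[chrom]]
  L <- nchar(chrom_seq)
  if (gene$strand == "+") {
    from <- max(1L, gene$start - length)
    to <- gene$start - 1L
    out <- if (to < from) "" else substr(chrom_seq, from, to)
  } else {
    from <- gene$end + 1L
    to <- min(L, gene$end + length)
    out <- if (to < from) "" else reverse_complement(substr(chrom_seq, from, to))
  }
  attr(out, "clipped") <- nchar(out) < length
  if (!is.null(gene$gene_id)) attr(out, "gene_id") <- gene$gene_id
  out
}

#' Read a TPM expression matrix from TSV
#'
#' First column = gene id, header row = sample ids. Values must be numeric,
#' finite and non-negative; row ids unique; rows rectangular.
#'
#' @param path TSV file.
#' @return Numeric matrix (genes x samples).
#' @export
read_tpm_matrix <- function(path) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) stop("TPM table needs a gene-id column plus samples",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene id '%s' in TPM table", ids[duplicated(ids)][1]),
         call. = FALSE)
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric or missing TPM at row '%s', column '%s'",
                   ids[i], names(body)[j]), call. = FALSE)
    }
    body[[j]] <- v
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (any(!is.finite(m))) stop("non-finite TPM value", call. = FALSE)
  if (any(m < 0)) stop("negative TPM value", call. = FALSE)
  m
}

#' Write a TPM (or any numeric) matrix as TSV
#'
#' @param m numeric matrix with row and column names.
#' @param path output file.
#' @param id_col name for the gene-id column (default "gene_id").
#' @return `path`, invisibly.
#' @export
write_tpm_matrix <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_versioned(df, path)
}
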