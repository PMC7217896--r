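# Expression-based pseudogene calling, heatmap-ready unit-variance scaling,
# PCA of sample profiles, and per-sub-family induction summaries.

#' Call expression-defined pseudogenes
#'
#' A gene whose TPM summed over all samples is strictly below `threshold`
#' (default 1) is a potential pseudogene.
#'
#' @param matrix TPM matrix (genes x samples).
#' @param genes gene ids to call (default: all rows). Ids absent from the
#'   matrix raise an error listing them.
#' @param threshold TPM-sum threshold (default 1.0).
#' @param strict use strict `<` (default TRUE, so a sum of exactly
#'   `threshold` is NOT a pseudogene).
#' @return Data frame: gene_id, tpm_sum, is_pseudogene.
#' @export
call_pseudogenes <- function(matrix, genes = rownames(matrix),
                             threshold = 1.0, strict = TRUE) {
  miss <- setdiff(genes, rownames(matrix))
  if (length(miss))
    stop(sprintf("genes absent from expression matrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  sums <- rowSums(matrix[genes, , drop = FALSE])
  data.frame(gene_id = genes, tpm_sum = unname(sums),
             is_pseudogene = if (strict) unname(sums) < threshold
                             else unname(sums) <= threshold,
             stringsAsFactors = FALSE)
}

#' Centre and scale rows to unit variance
#'
#' Each row is centred on its mean and divided by its sample standard
#' deviation (n - 1 denominator; set `sd_type = "population"` for n).
#' Constant rows become all-zero and are flagged in the `constant_rows`
#' attribute.
#'
#' @param matrix numeric matrix with >= 2 columns.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Scaled matrix with attribute `constant_rows`.
#' @export
scale_unit_variance <- function(matrix, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (ncol(matrix) < 2)
    stop("unit-variance scaling needs at least 2 columns", call. = FALSE)
  mu <- rowMeans(matrix)
  centred <- matrix - mu
  n <- ncol(matrix)
  ss <- rowSums(centred^2)
  sd <- sqrt(ss / (if (sd_type == "sample") n - 1 else n))
  constant <- sd == 0
  sd[constant] <- 1
  out <- centred / sd
  out[constant, ] <- 0
  attr(out, "constant_rows") <- rownames(matrix)[constant] %||%
    which(constant)
  out
}

#' Principal component analysis of expression profiles
#'
#' Column-centred SVD on a samples x features matrix. Variance explained
#' sums to 100% of total variance; component signs are fixed by making the
#' largest-magnitude loading of each component positive, so results are
#' invariant (not merely up to sign) under sample reordering.
#'
#' @param matrix samples x features numeric matrix (>= 2 samples).
#' @return An `hsp_pca` object: list with `scores` (samples x PCs),
#'   `loadings` (features x PCs), `variance_explained` (percent).
#' @export
pca_expression <- function(matrix) {
  if (nrow(matrix) < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  if (all(matrix == 0)) stop("all-zero matrix", call. = FALSE)
  centred <- sweep(matrix, 2, colMeans(matrix))
  sv <- svd(centred)
  d2 <- sv$d^2
  keep <- seq_len(min(nrow(matrix) - 1, ncol(matrix)))
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  loadings <- sv$v[, keep, drop = FALSE]
  for (k in keep) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  dimnames(scores) <- list(rownames(matrix), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(matrix), paste0("PC", keep))
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = 100 * d2[keep] / sum(d2)),
            class = "hsp_pca")
}

#' @export
print.hsp_pca <- function(x, ...) {
  ve <- round(x$variance_explained[seq_len(min(3, length(x$variance_explained)))], 1)
  cat(sprintf("hsp_pca: %d samples, PC1..%d; variance explained %s%%\n",
              nrow(x$scores), ncol(x$scores),
              paste(ve, collapse = "/")))
  invisible(x)
}

#' Per-sub-family, per-group mean scaled expression
#'
#' Rows are unit-variance scaled, then averaged over the member genes of
#' each sub-family and the samples of each group.
#'
#' @param matrix TPM matrix (genes x samples).
#' @param records data frame with gene_id and subfamily.
#' @param groups named character vector mapping sample id to group label
#'   (must cover all columns).
#' @return Matrix sub-family x group of mean scaled expression. Sub-families
#'   with no gene in the matrix are omitted with a message.
#' @export
induction_summary <- function(matrix, records, groups) {
  miss <- setdiff(colnames(matrix), names(groups))
  if (length(miss))
    stop(sprintf("samples without group annotation: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  scaled <- scale_unit_variance(matrix)
  fams <- sort(unique(records$subfamily))
  grps <- unique(unname(groups[colnames(matrix)]))
  out <- matrix(NA_real_, length(fams), length(grps),
                dimnames = list(fams, grps))
  drop_fam <- character()
  for (fam in fams) {
    ids <- intersect(records$gene_id[records$subfamily == fam],
                     rownames(scaled))
    if (!length(ids)) { drop_fam <- c(drop_fam, fam); next }
    for (grp in grps) {
      cols <- colnames(matrix)[groups[colnames(matrix)] == grp]
      out[fam, grp] <- mean(scaled[ids, cols, drop = FALSE])
    }
  }
  if (length(drop_fam)) {
    message("sub-families without expression rows omitted: ",
            paste(drop_fam, collapse = ", "))
    out <- out[!rownames(out) %in% drop_fam, , drop = FALSE]
  }
  out
}
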