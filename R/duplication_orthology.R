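# Tandem duplication detection, identical duplicates, progenitor top-hit
# orthology and per-chromosome synteny fractions.

#' Detect tandem duplication events among family genes
#'
#' A gene pair qualifies iff both genes lie on the same chromosome and
#' strand, their amino-acid identity (local-alignment percent identity)
#' exceeds `identity_min` strictly, and the number of annotated genes lying
#' strictly between them (over ALL annotated genes, not only family genes)
#' is below `max_intervening` strictly. Qualifying pairs are chained
#' transitively: arrays are the connected components of the pair graph.
#'
#' @param family_ids ids of family genes to test.
#' @param models `gene_models` for the whole annotation (intervening
#'   counts).
#' @param proteins named character vector of protein sequences covering the
#'   family genes.
#' @param identity_min strict identity threshold in percent (default 40).
#' @param max_intervening strict ceiling on intervening genes (default 5).
#' @param global_identity use global (alignment-length) instead of
#'   local-alignment identity; reserved switch, local is the default and
#'   only mode currently implemented.
#' @return List with `pairs` (gene1, gene2, chromosome, strand,
#'   identity_pct, intervening) and `arrays` (array_id, chromosome, strand,
#'   members comma string ordered by coordinate, size); plus `n_events_pairs`
#'   and `n_events_arrays` counts (the two readings of "a duplication
#'   event").
#' @export
find_tandem_duplications <- function(family_ids, models, proteins,
                                     identity_min = 40, max_intervening = 5,
                                     global_identity = FALSE) {
  g <- models$genes
  miss <- setdiff(family_ids, names(proteins))
  if (length(miss))
    stop(sprintf("protein missing for family gene '%s'", miss[1]),
         call. = FALSE)
  fam <- g[g$gene_id %in% family_ids & g$chromosome != "Un", , drop = FALSE]
  pairs <- list(); k <- 0L
  for (chrom in unique(fam$chromosome)) {
    fg <- fam[fam$chromosome == chrom, , drop = FALSE]
    fg <- fg[order(fg$start), ]
    allg <- g[g$chromosome == chrom, , drop = FALSE]
    if (nrow(fg) < 2) next
    for (i in seq_len(nrow(fg) - 1)) {
      for (j in (i + 1):nrow(fg)) {
        if (fg$strand[i] != fg$strand[j]) next
        left <- fg[i, ]; right <- fg[j, ]
        if (left$start > right$start) { tmp <- left; left <- right; right <- tmp }
        intervening <- sum(allg$start > left$end & allg$end < right$start)
        if (intervening >= max_intervening) next
        aln <- smith_waterman(proteins[[left$gene_id]],
                              proteins[[right$gene_id]], alphabet = "aa")
        if (is.na(aln$identity_pct) || aln$identity_pct <= identity_min) next
        k <- k + 1L
        pairs[[k]] <- data.frame(
          gene1 = left$gene_id, gene2 = right$gene_id, chromosome = chrom,
          strand = left$strand, identity_pct = aln$identity_pct,
          intervening = intervening, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, pairs) %||%
    data.frame(gene1 = character(), gene2 = character(),
               chromosome = character(), strand = character(),
               identity_pct = numeric(), intervening = integer(),
               stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  arrays <- chain_arrays(pairs, g)
  list(pairs = pairs, arrays = arrays,
       n_events_pairs = nrow(pairs), n_events_arrays = nrow(arrays))
}

# connected components of the qualifying-pair graph (union-find)
chain_arrays <- function(pairs, genes) {
  if (!nrow(pairs))
    return(data.frame(array_id = character(), chromosome = character(),
                      strand = character(), members = character(),
                      size = integer(), stringsAsFactors = FALSE))
  ids <- sort(unique(c(pairs$gene1, pairs$gene2)))
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(pairs))) {
    a <- find(match(pairs$gene1[r], ids)); b <- find(match(pairs$gene2[r], ids))
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_along(ids), find, numeric(1))
  rows <- lapply(split(ids, comp), function(members) {
    gi <- genes[match(members, genes$gene_id), ]
    members <- members[order(gi$start)]
    gi <- gi[order(gi$start), ]
    data.frame(chromosome = gi$chromosome[1], strand = gi$strand[1],
               members = paste(members, collapse = ","),
               size = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chromosome, out$members), , drop = FALSE]
  out <- data.frame(array_id = sprintf("TD%03d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Find identical protein duplicates within sub-families
#'
#' Reports every pair of proteins in the same sub-family whose sequences
#' are character-identical (100% identity, equal length).
#'
#' @param proteins named character vector.
#' @param subfamilies named character vector mapping gene id to sub-family
#'   label.
#' @return Data frame: gene1, gene2, subfamily (gene1 < gene2
#'   lexicographically).
#' @export
find_identical_duplicates <- function(proteins, subfamilies) {
  out <- list(); k <- 0L
  for (fam in unique(subfamilies)) {
    ids <- names(subfamilies)[subfamilies == fam]
    ids <- intersect(ids, names(proteins))
    if (length(ids) < 2) next
    groups <- split(ids, unname(proteins[ids]))
    for (grp in groups) {
      if (length(grp) < 2) next
      grp <- sort(grp)
      cmb <- utils::combn(grp, 2)
      for (c_i in seq_len(ncol(cmb))) {
        k <- k + 1L
        out[[k]] <- data.frame(gene1 = cmb[1, c_i], gene2 = cmb[2, c_i],
                               subfamily = fam, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(gene1 = character(), gene2 = character(),
               subfamily = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res[order(res$gene1, res$gene2), , drop = FALSE]
}

#' Top-hit ortholog search between CDS sets
#'
#' Each query CDS is aligned (nucleotide Smith-Waterman) against every
#' subject CDS; the best-bit-score subject passing both thresholds
#' (`e_value <= e_max`, `bit_score >= bit_min`) is reported as the top-hit
#' ortholog. Ties are broken by lower e-value, then lexical subject id.
#'
#' @param query_cds,subject_cds named character vectors of CDS sequences.
#' @param e_max e-value ceiling (default 1e-10).
#' @param bit_min bit-score floor, inclusive (default 150).
#' @return Data frame of `OrthologPair`s: query_id, subject_id,
#'   identity_pct, bit_score, e_value.
#' @export
find_orthologs <- function(query_cds, subject_cds, e_max = 1e-10,
                           bit_min = 150) {
  db_len <- sum(nchar(subject_cds))
  out <- list(); k <- 0L
  for (q in seq_along(query_cds)) {
    stats <- alignment_stats(default_stats("nt")$lambda,
                             default_stats("nt")$K,
                             search_space = nchar(query_cds[[q]]) * db_len)
    best <- NULL
    for (s in seq_along(subject_cds)) {
      r <- smith_waterman(query_cds[[q]], subject_cds[[s]], alphabet = "nt",
                          stats = stats, query_id = names(query_cds)[q],
                          subject_id = names(subject_cds)[s])
      if (is.na(r$e_value) || r$e_value > e_max || r$bit_score < bit_min) next
      if (is.null(best) ||
          r$bit_score > best$bit_score ||
          (r$bit_score == best$bit_score && r$e_value < best$e_value) ||
          (r$bit_score == best$bit_score && r$e_value == best$e_value &&
             r$subject_id < best$subject_id)) best <- r
    }
    if (!is.null(best)) { k <- k + 1L; out[[k]] <- best }
  }
  res <- do.call(rbind, out) %||% smith_waterman("A", "A")[0, ]
  rownames(res) <- NULL
  res[, c("query_id", "subject_id", "identity_pct", "bit_score", "e_value")]
}

#' Per-chromosome synteny fractions of ortholog pairs
#'
#' An ortholog pair is syntenic when the progenitor (query) gene lies on the
#' chromosome that corresponds to the family (subject) gene's chromosome
#' under `chromosome_map`. The per-chromosome fraction is the count of
#' syntenic ortholog pairs divided by the count of family genes on that
#' chromosome. Family chromosomes absent from the map make their pairs
#' non-syntenic (with a message).
#'
#' @param pairs data frame from [find_orthologs()] (query = progenitor,
#'   subject = family gene).
#' @param subject_chrom named chromosome vector for family genes.
#' @param query_chrom named chromosome vector for progenitor genes.
#' @param chromosome_map data frame with columns subject_chromosome,
#'   query_chromosome.
#' @return Data frame: chromosome, n_family, n_syntenic, fraction.
#' @export
synteny_fraction <- function(pairs, subject_chrom, query_chrom,
                             chromosome_map) {
  stopifnot(all(c("subject_chromosome", "query_chromosome") %in%
                  names(chromosome_map)))
  chroms <- chromosome_order(unique(subject_chrom[subject_chrom != "Un"]))
  if (!length(chroms))
    return(data.frame(chromosome = character(), n_family = integer(),
                      n_syntenic = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE))
  rows <- lapply(chroms, function(chrom) {
    fam_here <- names(subject_chrom)[subject_chrom == chrom]
    expected <- chromosome_map$query_chromosome[
      chromosome_map$subject_chromosome == chrom]
    if (!length(expected)) {
      message(sprintf("chromosome '%s' absent from correspondence map; ",
                      chrom), "its orthologs counted non-syntenic")
      expected <- NA_character_
    }
    p <- pairs[pairs$subject_id %in% fam_here, , drop = FALSE]
    syn <- sum(!is.na(expected[1]) &
                 query_chrom[p$query_id] %in% expected)
    data.frame(chromosome = chrom, n_family = length(fam_here),
               n_syntenic = syn,
               fraction = if (length(fam_here)) syn / length(fam_here) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
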