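# Merge the two evidence streams, classify candidates into the six HSP
# sub-families by signature-domain content, assign position-based names,
# and compute gene-structure statistics.

#' Signature-domain rules for the six HSP sub-families
#'
#' SHSP is defined by the alpha-crystallin domain (pfam00011); HSP40 by DnaJ
#' (pfam00226); HSP60, HSP70 and HSP90 by pfam00118 (Cpn60_TCP1), pfam00012
#' (HSP70) and pfam00183 (HSP90); HSP100 by the Clp machinery domains
#' (Clp_N pfam02861, ClpB_D2-small pfam10431 and the AAA variants pfam07724
#' / pfam07728), any `min_distinct` of which (default 2) must be present.
#' HSP90 additionally carries HATPase_c (pfam02518) as an expected auxiliary
#' domain whose absence is recorded, not disqualifying.
#'
#' @param hsp100_min_distinct distinct required domains demanded for an
#'   HSP100 call (default 2).
#' @return Data frame with columns subfamily, required (list), auxiliary
#'   (list), min_distinct.
#' @export
subfamily_rules <- function(hsp100_min_distinct = 2) {
  rules <- data.frame(
    subfamily = c("SHSP", "HSP40", "HSP60", "HSP70", "HSP90", "HSP100"),
    min_distinct = c(1, 1, 1, 1, 1, hsp100_min_distinct),
    stringsAsFactors = FALSE
  )
  rules$required <- list(
    "pfam00011", "pfam00226", "pfam00118", "pfam00012", "pfam00183",
    c("pfam02861", "pfam10431", "pfam07724", "pfam07728"))
  rules$auxiliary <- list(character(), character(), character(), character(),
                          "pfam02518", character())
  rules
}

#' Merge domain-scan and homology evidence into confirmed candidates
#'
#' The candidate set is the union of the protein ids carried by both
#' evidence streams; candidates lacking any confirmed required signature
#' domain (per `rules`) in the domain-hit table are dropped (the
#' domain-confirmation step).
#'
#' @param domain_hits data frame from [scan_proteome()].
#' @param homology_hits filtered data frame from [homology_search()] (the
#'   `subject_id` column names the candidate).
#' @param rules from [subfamily_rules()].
#' @return Character vector of confirmed candidate protein ids (sorted).
#' @export
merge_candidates <- function(domain_hits, homology_hits,
                             rules = subfamily_rules()) {
  cand <- union(domain_hits$protein_id, homology_hits$subject_id)
  if (!length(cand)) return(character())
  confirmed <- vapply(cand, function(id) {
    doms <- unique(domain_hits$domain_id[domain_hits$protein_id == id])
    any(vapply(seq_len(nrow(rules)), function(r) {
      sum(rules$required[[r]] %in% doms) >= rules$min_distinct[r]
    }, logical(1)))
  }, logical(1))
  sort(cand[confirmed])
}

#' Assign a sub-family label from a protein's domain hits
#'
#' The rule whose required-domain condition is met wins; when several rules
#' match (chimeric domain content) the one with the highest summed required
#' bit score is chosen and the conflict recorded. Absence of an expected
#' auxiliary domain (e.g. HATPase_c on HSP90) is flagged.
#'
#' @param hits domain-hit data frame for one protein.
#' @param rules from [subfamily_rules()].
#' @return List: `subfamily` (label or NA for unclassified), `aux_missing`
#'   (character vector), `conflict` (logical), `evidence_domains`.
#' @export
assign_subfamily <- function(hits, rules = subfamily_rules()) {
  doms <- unique(hits$domain_id)
  match_rows <- which(vapply(seq_len(nrow(rules)), function(r) {
    sum(rules$required[[r]] %in% doms) >= rules$min_distinct[r]
  }, logical(1)))
  if (!length(match_rows))
    return(list(subfamily = NA_character_, aux_missing = character(),
                conflict = FALSE, evidence_domains = doms))
  conflict <- length(match_rows) > 1
  if (conflict) {
    score <- vapply(match_rows, function(r)
      sum(hits$bit_score[hits$domain_id %in% rules$required[[r]]]),
      numeric(1))
    match_rows <- match_rows[which.max(score)]
  }
  r <- match_rows[1]
  aux <- rules$auxiliary[[r]]
  list(subfamily = rules$subfamily[r],
       aux_missing = setdiff(aux, doms),
       conflict = conflict,
       evidence_domains = doms)
}

#' Classify a set of confirmed candidates
#'
#' @param candidates character vector of protein/gene ids.
#' @param domain_hits domain-hit data frame covering the candidates.
#' @param rules from [subfamily_rules()].
#' @return Data frame: gene_id, subfamily, aux_missing (comma string),
#'   conflict, domains (comma string). Unclassifiable candidates get
#'   subfamily NA.
#' @export
classify_candidates <- function(candidates, domain_hits,
                                rules = subfamily_rules()) {
  rows <- lapply(candidates, function(id) {
    a <- assign_subfamily(domain_hits[domain_hits$protein_id == id, ], rules)
    data.frame(gene_id = id, subfamily = a$subfamily,
               aux_missing = paste(a$aux_missing, collapse = ","),
               conflict = a$conflict,
               domains = paste(sort(a$evidence_domains), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(gene_id = character(), subfamily = character(),
               aux_missing = character(), conflict = logical(),
               domains = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assign position-based names to classified family members
#'
#' Within each sub-family, placed genes are ordered by chromosome (natural
#' order 1A, 1B, 1D, ..., 7D) and ascending start coordinate (annotation
#' origin taken as the short-arm telomere) and numbered from 1; unplaced
#' genes (chromosome "Un") are numbered last, ordered by id. The name
#' prefix is "TaS" for the small-HSP sub-family (yielding e.g. "TaSHSP3")
#' and "Ta" otherwise (e.g. "TaHSP70.2"). Genes with several annotated
#' mRNAs receive one name per isoform, the shared gene number with a ".k"
#' suffix in annotation order.
#'
#' @param records data frame with gene_id and subfamily.
#' @param models a `gene_models` object covering the records.
#' @return `records` with assigned_name added, plus an `isoforms` attribute
#'   (data frame mrna_id, gene_id, isoform_index, isoform_name) when the
#'   annotation has multi-mRNA genes.
#' @export
assign_names <- function(records, models) {
  if (anyDuplicated(records$gene_id))
    stop("duplicate gene ids in records", call. = FALSE)
  g <- models$genes
  idx <- match(records$gene_id, g$gene_id)
  if (anyNA(idx))
    stop(sprintf("no gene model for '%s'",
                 records$gene_id[which(is.na(idx))[1]]), call. = FALSE)
  records$chromosome <- g$chromosome[idx]
  records$start <- g$start[idx]
  records$end <- g$end[idx]
  records$strand <- g$strand[idx]
  records$subgenome <- g$subgenome[idx]

  chrom_rank <- match(records$chromosome,
                      chromosome_order(records$chromosome))
  unplaced <- records$chromosome == "Un"
  records$assigned_name <- rep(NA_character_, nrow(records))
  for (fam in unique(records$subfamily)) {
    sel <- which(records$subfamily == fam)
    ord <- sel[order(unplaced[sel], chrom_rank[sel], records$start[sel],
                     records$gene_id[sel])]
    n <- seq_along(ord)
    base <- if (fam == "SHSP") paste0("TaSHSP", n)
            else paste0("Ta", fam, ".", n)
    records$assigned_name[ord] <- base
  }

  # isoform names for multi-mRNA genes
  if (!is.null(models$mrnas) && nrow(models$mrnas)) {
    mr <- models$mrnas[models$mrnas$gene_id %in% records$gene_id, ,
                       drop = FALSE]
    counts <- table(mr$gene_id)
    multi <- names(counts)[counts > 1]
    if (length(multi)) {
      mr <- mr[mr$gene_id %in% multi, , drop = FALSE]
      mr$isoform_index <- stats::ave(seq_len(nrow(mr)), mr$gene_id,
                                     FUN = seq_along)
      mr$isoform_name <- paste0(
        records$assigned_name[match(mr$gene_id, records$gene_id)],
        ".", mr$isoform_index)
      attr(records, "isoforms") <-
        mr[, c("mrna_id", "gene_id", "isoform_index", "isoform_name")]
    }
  }
  records
}

#' Gene-structure statistics
#'
#' Introns are the gaps between consecutive exons of the representative
#' transcript; `gene_length = end - start + 1`; a gene is intronless iff it
#' has a single exon.
#'
#' @param models a `gene_models` object.
#' @return Data frame: gene_id, gene_length, exon_count, intron_count,
#'   intron_lengths (comma string), max_intron, intronless, strand.
#' @export
structure_stats <- function(models) {
  g <- models$genes
  if (!nrow(g))
    return(data.frame(gene_id = character(), gene_length = integer(),
                      exon_count = integer(), intron_count = integer(),
                      intron_lengths = character(), max_intron = integer(),
                      intronless = logical(), strand = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(g)), function(i) {
    e <- models$exons[models$exons$gene_id == g$gene_id[i], , drop = FALSE]
    e <- e[order(e$start), ]
    if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
      stop(sprintf("overlapping exons in gene '%s'", g$gene_id[i]),
           call. = FALSE)
    introns <- if (nrow(e) > 1) e$start[-1] - e$end[-nrow(e)] - 1L
               else integer()
    data.frame(
      gene_id = g$gene_id[i],
      gene_length = g$end[i] - g$start[i] + 1L,
      exon_count = nrow(e), intron_count = length(introns),
      intron_lengths = paste(introns, collapse = ","),
      max_intron = if (length(introns)) max(introns) else 0L,
      intronless = length(introns) == 0L,
      strand = g$strand[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Chromosome / sub-genome / sub-family distribution summary
#'
#' @param records named records (from [assign_names()]).
#' @return List with `per_chromosome`, `per_subgenome`, `per_subfamily`
#'   count tables, `by_chromosome_subfamily` cross table, and
#'   `n_unplaced`. Unplaced genes are excluded from positional counts.
#' @export
distribution_summary <- function(records) {
  placed <- records[records$chromosome != "Un", , drop = FALSE]
  chroms <- chromosome_order(placed$chromosome)
  per_chrom <- table(factor(placed$chromosome, levels = chroms))
  per_sub <- table(placed$subgenome)
  per_fam <- table(records$subfamily)
  cross <- table(factor(placed$chromosome, levels = chroms),
                 placed$subfamily)
  list(per_chromosome = per_chrom, per_subgenome = per_sub,
       per_subfamily = per_fam, by_chromosome_subfamily = cross,
       n_unplaced = sum(records$chromosome == "Un"))
}

#' Write the master family table
#'
#' @param records named records.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(records, path) {
  cols <- intersect(c("gene_id", "assigned_name", "subfamily", "chromosome",
                      "start", "end", "strand", "subgenome", "domains",
                      "aux_missing", "conflict"), names(records))
  write_tsv_versioned(records[, cols], path)
}
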