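# Synthetic miniature-genome generator with machine-readable ground truth.
# Emulates the statistical structure the pipeline assumes: multi-chromosome
# annotated genome, domain-bearing family genes across the six sub-families,
# composition-matched decoys, tandem arrays with 0-4 intervening decoys,
# expression-silent pseudogenes, promoters with planted IUPAC motifs, and
# divergent progenitor CDS sets per sub-genome.

#' Configuration for the synthetic dataset generator
#'
#' Defaults define the package's reference validation conditions: 6
#' chromosomes of 1 Mb, 60 family genes across the six sub-families in
#' roughly the proportions seen in hexaploid wheat, 140 decoy genes, 20%
#' planted-domain divergence, tandem arrays of 2/3/5/7 genes, 20%
#' expression-silent pseudogenes, 12 expression samples in four tissue
#' groups, and 5% progenitor CDS divergence.
#'
#' @param n_chromosomes number of chromosomes (named 1A, 1B, 1D, 2A, ...).
#' @param chromosome_length chromosome length in bp.
#' @param n_family_genes planted family genes.
#' @param n_decoy_genes decoy genes (no domain).
#' @param subfamily_mix named proportions over the six sub-families
#'   (must sum to 1).
#' @param domain_divergence expected substituted fraction in planted
#'   domains, in [0, 0.5].
#' @param tandem_array_sizes planted array sizes, each in 2..7.
#' @param pseudogene_fraction fraction of family genes with silent
#'   expression, in [0, 1].
#' @param n_samples expression columns (multiple of 4; grouped into grain /
#'   leaf / root / spike).
#' @param motif_plant_counts list with elements `family` and `decoy`: named
#'   integer vectors of planted occurrences per promoter of that class
#'   (names must be catalogue motifs).
#' @param progenitor_divergence per-site nucleotide substitution
#'   probability for progenitor CDS, in [0, 1].
#' @param seed integer random seed; fully determines the bundle.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_chromosomes = 6, chromosome_length = 1e6,
                             n_family_genes = 60, n_decoy_genes = 140,
                             subfamily_mix = c(SHSP = 0.22, HSP40 = 0.36,
                                               HSP60 = 0.13, HSP70 = 0.15,
                                               HSP90 = 0.03, HSP100 = 0.11),
                             domain_divergence = 0.2,
                             tandem_array_sizes = c(2, 3, 5, 7),
                             pseudogene_fraction = 0.2,
                             n_samples = 12,
                             motif_plant_counts = list(
                               family = c(HSE = 2, ABRE = 1, `CAAT-box` = 2,
                                          `G-box` = 1),
                               decoy = c()),
                             progenitor_divergence = 0.05,
                             seed = 1) {
  stopifnot(n_chromosomes >= 1, chromosome_length >= 10000,
            n_family_genes >= 0, n_decoy_genes >= 0)
  if (abs(sum(subfamily_mix) - 1) > 1e-8 || any(subfamily_mix < 0) ||
      any(subfamily_mix > 1))
    stop("subfamily_mix must be proportions summing to 1", call. = FALSE)
  stopifnot(all(names(subfamily_mix) %in%
                  c("SHSP", "HSP40", "HSP60", "HSP70", "HSP90", "HSP100")))
  if (length(tandem_array_sizes) &&
      !all(tandem_array_sizes %in% 2:7))
    stop("tandem_array_sizes must lie in 2..7", call. = FALSE)
  stopifnot(domain_divergence >= 0, domain_divergence <= 0.5,
            pseudogene_fraction >= 0, pseudogene_fraction <= 1,
            progenitor_divergence >= 0, progenitor_divergence <= 1,
            n_samples >= 4)
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length = as.integer(chromosome_length),
    n_family_genes = as.integer(n_family_genes),
    n_decoy_genes = as.integer(n_decoy_genes),
    subfamily_mix = subfamily_mix,
    domain_divergence = domain_divergence,
    tandem_array_sizes = as.integer(tandem_array_sizes),
    pseudogene_fraction = pseudogene_fraction,
    n_samples = as.integer(n_samples),
    motif_plant_counts = motif_plant_counts,
    progenitor_divergence = progenitor_divergence,
    seed = as.integer(seed)), class = "synthetic_config")
}

#' Substitute residues of a sequence at a fixed per-site rate
#'
#' Each position is independently substituted with probability `rate` to a
#' different symbol of the alphabet (never the original one); length is
#' preserved. An empty sequence returns empty.
#'
#' @param seq residue string.
#' @param rate substitution probability in [0, 1].
#' @param alphabet character vector of symbols (default amino acids).
#' @param seed optional private seed (leaves the caller's RNG untouched).
#' @return Mutated string.
#' @export
mutate_sequence <- function(seq, rate, alphabet = AA_ALPHABET, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!nchar(seq)) return("")
  run <- function() {
    ch <- seq_chars(seq)
    hit <- which(stats::runif(length(ch)) < rate)
    for (p in hit) {
      others <- alphabet[alphabet != ch[p]]
      ch[p] <- others[sample.int(length(others), 1)]
    }
    paste(ch, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Bundled domain seed alignments
#'
#' Reads the artificial aligned seed sequences bundled for each signature
#' domain id (desk-scale stand-ins for real domain family alignments,
#' synthetic by construction).
#'
#' @param dir directory of `<domain_id>.afa` files (default: bundled).
#' @return Named list of aligned character vectors.
#' @export
domain_alignments <- function(dir = system.file("extdata", "domains",
                                                package = "hspminer")) {
  files <- sort(list.files(dir, pattern = "\\.afa$", full.names = TRUE))
  out <- lapply(files, function(f) unname(read_fasta(f, "aa")))
  names(out) <- sub("\\.afa$", "", basename(files))
  out
}

#' Build the PSSM profile database from seed alignments
#'
#' @param alignments from [domain_alignments()].
#' @param ... passed to [build_pssm()].
#' @return Named list of `pssm_profile`s.
#' @export
domain_profiles <- function(alignments = domain_alignments(), ...) {
  mapply(function(aln, id) build_pssm(aln, domain_id = id, ...),
         alignments, names(alignments), SIMPLIFY = FALSE)
}

#' Seed proteins for the homology evidence stream
#'
#' One "known family member" per signature domain: the domain consensus
#' sequence (standing in for curated family sequences from related
#' species).
#'
#' @param alignments from [domain_alignments()].
#' @return Named character vector of seed proteins.
#' @export
hsp_seed_proteins <- function(alignments = domain_alignments()) {
  vapply(alignments, consensus_sequence, character(1))
}

# domains planted per subfamily (HSP90 aux on most genes; HSP100 gets three
# of its required set)
planted_domain_set <- function(subfamily, gene_index) {
  switch(subfamily,
    SHSP = "pfam00011",
    HSP40 = "pfam00226",
    HSP60 = "pfam00118",
    HSP70 = "pfam00012",
    HSP90 = if (gene_index %% 4 == 0) "pfam00183"
            else c("pfam00183", "pfam02518"),
    HSP100 = c("pfam02861",
               if (gene_index %% 2 == 0) "pfam07724" else "pfam07728",
               "pfam10431"))
}

# intron count sampler per gene class
sample_intron_count <- function(class) {
  if (class == "SHSP") sample(0:2, 1, prob = c(0.7, 0.2, 0.1))
  else if (class %in% c("HSP60", "HSP90")) sample(2:8, 1)
  else if (class == "decoy") sample(0:3, 1)
  else sample(0:5, 1)
}

random_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                               collapse = "")
random_nt_raw <- function(n) sample(charToRaw("ACGT"), n, replace = TRUE)

reverse_translate <- function(protein) {
  paste0(paste(CODON_OF[seq_chars(protein)], collapse = ""), STOP_CODON)
}

# vectorized IUPAC motif counter used for ground-truth counts (independent
# of the Biostrings-based scanner)
count_motif_truth <- function(seq, pattern, both_strands = TRUE) {
  count_one <- function(s, pat) {
    n <- nchar(s); L <- nchar(pat)
    if (L > n) return(0L)
    ch <- seq_chars(s)
    allowed <- IUPAC_NT[seq_chars(pat)]
    ok <- rep(TRUE, n - L + 1)
    for (k in seq_len(L)) ok <- ok & ch[k:(n - L + k)] %in% allowed[[k]]
    sum(ok)
  }
  n <- count_one(seq, pattern)
  if (both_strands && !is_palindromic_pattern(pattern))
    n <- n + count_one(seq, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pattern))))
  n
}

#' Generate a synthetic annotated-genome bundle with ground truth
#'
#' Writes genome FASTA, GFF3, proteome FASTA, CDS FASTA, TPM matrix TSV,
#' progenitor CDS FASTAs (one per sub-genome), a chromosome correspondence
#' map and truth tables into `dir`, and returns them in memory. The same
#' seed yields byte-identical files. An impossible layout (genes exceeding
#' the chromosome length) fails before any file is written.
#'
#' Layout guarantees: tandem-array members share strand and chromosome with
#' 0-4 planted intervening decoys (cycling through the boundary values);
#' family genes of different layout units are separated so that no
#' unplanned pair satisfies the tandem rule; the second member of every
#' planted array is an exact protein copy of the first (an identical
#' duplicate); pseudogene TPM rows sum below 1 and all other family rows
#' sum above 1; truth motif counts are the actual occurrence counts of each
#' catalogue motif in the final promoter (planting plus background),
#' counted with an internal matcher.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created).
#' @param motifs CARE catalogue (default bundled).
#' @return A `hsp_dataset` list: `paths` (named file paths), `genome`,
#'   `proteome`, `cds`, `models`, `tpm`, `progenitors`, `truth` (list of
#'   data frames: genes, motif_counts, identical_pairs, sample_groups,
#'   induction).
#' @export
generate_dataset <- function(config, dir, motifs = read_care_motifs()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, generate_dataset_impl(config, dir, motifs))
}

generate_dataset_impl <- function(config, dir, motifs) {
  alns <- domain_alignments()
  consensus <- vapply(alns, consensus_sequence, character(1))
  chroms <- paste0(rep(seq_len(ceiling(config$n_chromosomes / 3)),
                       each = 3), c("A", "B", "D"))[
                         seq_len(config$n_chromosomes)]

  fams <- names(config$subfamily_mix)
  counts <- diff(c(0, round(cumsum(config$subfamily_mix *
                                     config$n_family_genes))))
  names(counts) <- fams

  # ---- assign arrays to sub-families (largest quotas first) -------------
  sizes <- sort(config$tandem_array_sizes, decreasing = TRUE)
  remaining <- counts
  arrays <- list()
  for (s in sizes) {
    fam <- names(remaining)[order(-remaining)][1]
    if (remaining[fam] < s) next  # quota too small; skip this array
    arrays[[length(arrays) + 1]] <- list(subfamily = fam, size = s)
    remaining[fam] <- remaining[fam] - s
  }
  singles <- rep(names(remaining), remaining)

  # ---- layout units (arrays whole, singletons individual) ---------------
  units <- c(lapply(arrays, function(a) a),
             lapply(singles, function(f) list(subfamily = f, size = 1L)))
  if (length(units) > 1) units <- units[sample.int(length(units))]
  unit_chrom <- rep(chroms, length.out = length(units))

  # ---- build gene payloads ----------------------------------------------
  gene_id_counter <- 0L
  new_gene_id <- function() {
    gene_id_counter <<- gene_id_counter + 1L
    sprintf("g%03d", gene_id_counter)
  }
  intervening_cycle <- c(0L, 1L, 2L, 3L, 4L)
  decoys_left <- config$n_decoy_genes
  make_decoy <- function() {
    if (decoys_left <= 0L) return(NULL)
    decoys_left <<- decoys_left - 1L
    list(gene_id = new_gene_id(), class = "decoy", subfamily = NA_character_,
         protein = paste0("M", random_aa(sample(120:360, 1))),
         planted_domains = character(), array_id = NA_character_)
  }
  fam_index <- 0L
  make_family_gene <- function(subfamily, array_id, protein = NULL,
                               domains = NULL) {
    fam_index <<- fam_index + 1L
    if (is.null(protein)) {
      domains <- planted_domain_set(subfamily, fam_index)
      dseqs <- vapply(domains, function(d)
        mutate_sequence(consensus[[d]], config$domain_divergence),
        character(1))
      protein <- paste0("M", random_aa(39),
                        paste(dseqs, collapse = random_aa(5)),
                        random_aa(40))
    }
    list(gene_id = new_gene_id(), class = subfamily, subfamily = subfamily,
         protein = protein, planted_domains = domains, array_id = array_id)
  }

  per_chrom_genes <- stats::setNames(
    lapply(chroms, function(x) list()), chroms)
  identical_pairs <- list()
  array_counter <- 0L
  icyc <- 0L
  next_intervening <- function() {
    icyc <<- icyc + 1L
    intervening_cycle[((icyc - 1L) %% length(intervening_cycle)) + 1L]
  }
  unit_strand_state <- stats::setNames(rep(TRUE, length(chroms)), chroms)

  for (u in seq_along(units)) {
    unit <- units[[u]]
    chrom <- unit_chrom[u]
    strand <- if (unit_strand_state[chrom]) "+" else "-"
    unit_strand_state[chrom] <- !unit_strand_state[chrom]
    glist <- per_chrom_genes[[chrom]]
    add <- function(g, s) {
      g$strand <- s
      glist[[length(glist) + 1]] <<- g
    }
    # separate units: two decoys (any strand) so no cross-unit pair can
    # satisfy the same-strand + <5-intervening rule given strand alternation
    if (length(glist) > 0) {
      for (k in 1:2) { d <- make_decoy(); if (!is.null(d)) add(d, sample(c("+", "-"), 1)) }
    }
    if (unit$size == 1L) {
      add(make_family_gene(unit$subfamily, NA_character_), strand)
    } else {
      array_counter <- array_counter + 1L
      aid <- sprintf("array%02d", array_counter)
      first <- make_family_gene(unit$subfamily, aid)
      add(first, strand)
      members <- first$gene_id
      for (k in 2:unit$size) {
        niv <- next_intervening()
        if (k > 2 && niv > 0) {
          for (z in seq_len(niv)) {
            d <- make_decoy(); if (!is.null(d)) add(d, sample(c("+", "-"), 1))
          }
        }
        if (k == 2) {
          m <- make_family_gene(unit$subfamily, aid, protein = first$protein,
                                domains = first$planted_domains)
          identical_pairs[[length(identical_pairs) + 1]] <-
            data.frame(gene1 = first$gene_id, gene2 = m$gene_id,
                       subfamily = unit$subfamily, stringsAsFactors = FALSE)
        } else {
          m <- make_family_gene(
            unit$subfamily, aid,
            protein = mutate_sequence(first$protein, 0.02),
            domains = first$planted_domains)
        }
        add(m, strand)
        members <- c(members, m$gene_id)
      }
    }
    per_chrom_genes[[chrom]] <- glist
  }
  # remaining decoys appended round-robin at chromosome ends
  rr <- 0L
  while (decoys_left > 0L) {
    chrom <- chroms[(rr %% length(chroms)) + 1L]; rr <- rr + 1L
    d <- make_decoy()
    d$strand <- sample(c("+", "-"), 1)
    per_chrom_genes[[chrom]][[length(per_chrom_genes[[chrom]]) + 1]] <- d
  }

  # ---- coordinates, exon structure, chromosome sequences ----------------
  spacer <- 1700L
  genome_raw <- stats::setNames(
    lapply(chroms, function(x) random_nt_raw(config$chromosome_length)),
    chroms)
  genes_rows <- list(); exons_rows <- list(); prot_out <- character()
  cds_out <- character()
  for (chrom in chroms) {
    cursor <- 3000L
    for (g in per_chrom_genes[[chrom]]) {
      cds <- reverse_translate(g$protein)
      n_intron <- sample_intron_count(if (g$class == "decoy") "decoy"
                                      else g$subfamily)
      n_exon <- n_intron + 1L
      clen <- nchar(cds)
      if (n_exon > 1) {
        cuts <- sort(sample(seq_len(clen - 1), n_exon - 1))
        piece_len <- diff(c(0L, cuts, clen))
        intron_len <- sample(60:400, n_intron, replace = TRUE)
      } else {
        piece_len <- clen
        intron_len <- integer()
      }
      start <- cursor + 1L
      pos <- start
      ex <- list()
      placed <- if (g$strand == "+") cds else reverse_complement(cds)
      # for minus strand, pieces of revcomp(CDS) fill exons left to right so
      # that revcomp of the ascending exon concatenation returns the CDS
      offset <- 0L
      for (e in seq_len(n_exon)) {
        plen <- piece_len[e]
        ex[[e]] <- c(pos, pos + plen - 1L)
        genome_raw[[chrom]][pos:(pos + plen - 1L)] <-
          charToRaw(substr(placed, offset + 1L, offset + plen))
        offset <- offset + plen
        pos <- pos + plen
        if (e < n_exon) pos <- pos + intron_len[e]
      }
      end <- pos - 1L
      if (end + spacer > config$chromosome_length)
        stop(sprintf("layout impossible: genes exceed chromosome %s length",
                     chrom), call. = FALSE)
      genes_rows[[length(genes_rows) + 1]] <- data.frame(
        gene_id = g$gene_id, chromosome = chrom, start = start, end = end,
        strand = g$strand, stringsAsFactors = FALSE)
      exons_rows[[length(exons_rows) + 1]] <- data.frame(
        gene_id = g$gene_id,
        start = vapply(ex, `[`, numeric(1), 1),
        end = vapply(ex, `[`, numeric(1), 2), stringsAsFactors = FALSE)
      prot_out[g$gene_id] <- g$protein
      cds_out[g$gene_id] <- cds
      cursor <- end + spacer
    }
  }
  genes_df <- do.call(rbind, genes_rows)
  exons_df <- do.call(rbind, exons_rows)

  # ---- plant promoter motifs --------------------------------------------
  gene_meta <- do.call(rbind, lapply(unlist(per_chrom_genes,
                                            recursive = FALSE), function(g)
    data.frame(gene_id = g$gene_id, class = g$class,
               subfamily = g$subfamily,
               planted_domains = paste(g$planted_domains, collapse = ","),
               array_id = g$array_id, stringsAsFactors = FALSE)))
  gene_meta <- gene_meta[match(genes_df$gene_id, gene_meta$gene_id), ]

  plant_counts_for <- function(class) {
    key <- if (class == "decoy") "decoy" else "family"
    pc <- config$motif_plant_counts[[key]]
    if (is.null(pc)) integer() else pc
  }
  promoter_len <- 1500L
  for (i in seq_len(nrow(genes_df))) {
    pc <- plant_counts_for(gene_meta$class[i])
    if (!length(pc)) next
    chrom <- genes_df$chromosome[i]
    if (genes_df$strand[i] == "+") {
      lo <- genes_df$start[i] - promoter_len; hi <- genes_df$start[i] - 1L
    } else {
      lo <- genes_df$end[i] + 1L; hi <- genes_df$end[i] + promoter_len
    }
    lo <- max(1L, lo); hi <- min(config$chromosome_length, hi)
    region <- rawToChar(genome_raw[[chrom]][lo:hi])
    if (genes_df$strand[i] == "-") region <- reverse_complement(region)
    taken <- rep(FALSE, nchar(region))
    for (m in names(pc)) {
      pat <- motifs$pattern[motifs$name == m]
      if (!length(pat)) stop(sprintf("motif '%s' not in catalogue", m),
                             call. = FALSE)
      L <- nchar(pat)
      for (rep_i in seq_len(pc[[m]])) {
        for (try in 1:200) {
          off <- sample.int(nchar(region) - L + 1L, 1)
          if (!any(taken[off:(off + L - 1L)])) break
        }
        taken[off:(off + L - 1L)] <- TRUE
        inst <- paste(vapply(IUPAC_NT[seq_chars(pat)], function(opts)
          opts[sample.int(length(opts), 1)], character(1)), collapse = "")
        substr(region, off, off + L - 1L) <- inst
      }
    }
    out_region <- if (genes_df$strand[i] == "-") reverse_complement(region)
                  else region
    genome_raw[[chrom]][lo:hi] <- charToRaw(out_region)
  }

  genome <- vapply(genome_raw, rawToChar, character(1))
  models <- gene_models(genes_df, exons_df)

  # ground-truth motif counts = actual occurrences in the final promoters
  fam_ids <- genes_df$gene_id[gene_meta$class != "decoy"]
  motif_counts <- matrix(0L, length(fam_ids), nrow(motifs),
                         dimnames = list(fam_ids, motifs$name))
  for (gid in fam_ids) {
    gi <- which(genes_df$gene_id == gid)
    prom <- extract_promoter(genome, genes_df[gi, ], promoter_len)
    for (m in seq_len(nrow(motifs)))
      motif_counts[gid, m] <- count_motif_truth(as.character(prom),
                                                motifs$pattern[m])
  }

  # ---- expression matrix -------------------------------------------------
  n_per_group <- config$n_samples %/% 4
  groups <- rep(c("grain", "leaf", "root", "spike"),
                length.out = config$n_samples)
  groups <- sort(groups)
  sample_ids <- unlist(lapply(unique(groups), function(gname) {
    k <- sum(groups == gname)
    sprintf("%s_z%02d_r%d", gname, 10 * seq_len(k) + 61, seq_len(k))
  }))
  sample_groups <- stats::setNames(sub("_.*$", "", sample_ids), sample_ids)
  induction <- list(SHSP = c(grain = 8), HSP70 = c(spike = 6),
                    HSP40 = c(leaf = 5), HSP100 = c(spike = 4))

  n_pseudo <- floor(config$pseudogene_fraction * length(fam_ids))
  pseudo_ids <- if (n_pseudo > 0) sample(fam_ids, n_pseudo) else character()
  tpm <- matrix(0, nrow(genes_df), config$n_samples,
                dimnames = list(genes_df$gene_id, sample_ids))
  for (i in seq_len(nrow(genes_df))) {
    gid <- genes_df$gene_id[i]
    if (gid %in% pseudo_ids) {
      tpm[i, ] <- stats::runif(config$n_samples,
                               0, 0.9 / config$n_samples)
    } else {
      base <- stats::rlnorm(1, meanlog = 2, sdlog = 0.6)
      row <- base * stats::rlnorm(config$n_samples, 0, 0.3)
      fam <- gene_meta$subfamily[i]
      if (!is.na(fam) && fam %in% names(induction)) {
        for (gname in names(induction[[fam]])) {
          sel <- sample_groups[colnames(tpm)] == gname
          row[sel] <- row[sel] * induction[[fam]][gname]
        }
      }
      if (sum(row) < 1) row <- row * 1.5 / sum(row)
      tpm[i, ] <- row
    }
  }

  # ---- progenitor CDS sets ----------------------------------------------
  progenitors <- list()
  prog_chrom_rows <- list()
  map_rows <- list()
  for (sg in c("A", "B", "D")) {
    on_sg <- genes_df$gene_id[gene_meta$class != "decoy" &
                                subgenome_of(genes_df$chromosome) == sg]
    if (!length(on_sg)) next
    seqs <- character(); chrom_of <- character()
    for (gid in on_sg) {
      pid <- sprintf("pg%s_%s", sg, gid)
      seqs[pid] <- mutate_sequence(cds_out[[gid]],
                                   config$progenitor_divergence,
                                   NT_ALPHABET)
      chrom_of[pid] <- gsub("[A-Z]", "",
                            genes_df$chromosome[genes_df$gene_id == gid])
    }
    progenitors[[sg]] <- list(cds = seqs, chromosomes = chrom_of)
    prog_chrom_rows[[sg]] <- data.frame(
      ortholog_id = names(chrom_of), species = paste0("progenitor_", sg),
      chromosome = unname(chrom_of), stringsAsFactors = FALSE)
    sgchroms <- unique(genes_df$chromosome[
      subgenome_of(genes_df$chromosome) == sg])
    map_rows[[sg]] <- data.frame(
      subject_chromosome = sgchroms,
      query_chromosome = gsub("[A-Z]", "", sgchroms),
      species = paste0("progenitor_", sg), stringsAsFactors = FALSE)
  }
  prog_of_gene <- stats::setNames(rep(NA_character_, nrow(genes_df)),
                                  genes_df$gene_id)
  for (sg in names(progenitors)) {
    ids <- names(progenitors[[sg]]$cds)
    prog_of_gene[sub("^pg[A-Z]_", "", ids)] <- ids
  }

  # ---- truth tables ------------------------------------------------------
  truth_genes <- data.frame(
    gene_id = genes_df$gene_id,
    is_family_member = gene_meta$class != "decoy",
    subfamily = gene_meta$subfamily,
    planted_domains = gene_meta$planted_domains,
    tandem_array_id = gene_meta$array_id,
    is_pseudogene = genes_df$gene_id %in% pseudo_ids &
      gene_meta$class != "decoy",
    progenitor_ortholog_id = unname(prog_of_gene[genes_df$gene_id]),
    chromosome = genes_df$chromosome, start = genes_df$start,
    end = genes_df$end, strand = genes_df$strand,
    stringsAsFactors = FALSE)
  identical_df <- do.call(rbind, identical_pairs) %||%
    data.frame(gene1 = character(), gene2 = character(),
               subfamily = character(), stringsAsFactors = FALSE)

  # ---- write everything (only after full in-memory construction) ---------
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fasta"),
    gff = file.path(dir, "annotation.gff3"),
    proteome = file.path(dir, "proteome.fasta"),
    cds = file.path(dir, "cds.fasta"),
    tpm = file.path(dir, "tpm.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_motifs = file.path(dir, "truth_motif_counts.tsv"),
    truth_identical = file.path(dir, "truth_identical_pairs.tsv"),
    chromosome_map = file.path(dir, "chromosome_map.tsv"),
    progenitor_chromosomes = file.path(dir, "progenitor_chromosomes.tsv"))
  write_fasta(genome, paths[["genome"]])
  write_gff3(models, paths[["gff"]])
  write_fasta(prot_out[genes_df$gene_id], paths[["proteome"]])
  write_fasta(cds_out[genes_df$gene_id], paths[["cds"]])
  write_tpm_matrix(tpm, paths[["tpm"]])
  write_tsv_versioned(truth_genes, paths[["truth_genes"]])
  write_tpm_matrix(motif_counts, paths[["truth_motifs"]])
  write_tsv_versioned(identical_df, paths[["truth_identical"]])
  map_df <- do.call(rbind, map_rows) %||%
    data.frame(subject_chromosome = character(),
               query_chromosome = character(), species = character(),
               stringsAsFactors = FALSE)
  prog_chrom_df <- do.call(rbind, prog_chrom_rows) %||%
    data.frame(ortholog_id = character(), species = character(),
               chromosome = character(), stringsAsFactors = FALSE)
  write_tsv_versioned(map_df, paths[["chromosome_map"]])
  write_tsv_versioned(prog_chrom_df, paths[["progenitor_chromosomes"]])
  for (sg in names(progenitors)) {
    p <- file.path(dir, sprintf("progenitor_%s.fasta", sg))
    write_fasta(progenitors[[sg]]$cds, p)
    paths[[paste0("progenitor_", sg)]] <- p
  }

  structure(list(
    paths = paths, genome = genome, proteome = prot_out[genes_df$gene_id],
    cds = cds_out[genes_df$gene_id], models = models, tpm = tpm,
    progenitors = progenitors,
    chromosome_map = map_df,
    truth = list(genes = truth_genes, motif_counts = motif_counts,
                 identical_pairs = identical_df,
                 sample_groups = sample_groups, induction = induction,
                 pseudogene_ids = sort(pseudo_ids))),
    class = "hsp_dataset")
}

#' @export
print.hsp_dataset <- function(x, ...) {
  tg <- x$truth$genes
  cat(sprintf(paste0("hsp_dataset: %d genes (%d family, %d decoy) on %d",
                     " chromosomes; %d pseudogenes, %d tandem arrays\n"),
              nrow(tg), sum(tg$is_family_member),
              sum(!tg$is_family_member),
              length(unique(tg$chromosome)),
              sum(tg$is_pseudogene),
              length(unique(stats::na.omit(tg$tandem_array_id)))))
  invisible(x)
}
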