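# End-to-end orchestration: configuration, staged execution with a run
# report, and self-validation against the synthetic generator's truth.

#' Pipeline configuration
#'
#' Collects input paths and every stage threshold, with the standard
#' defaults: domain-scan and homology e-value 1e-4, homology bit score
#' strictly above 100, tandem identity strictly above 40% with strictly
#' fewer than 5 intervening genes, pseudogene TPM sum strictly below 1,
#' ortholog e-value 1e-10 with bit score at least 150, and 1500 bp
#' promoters.
#'
#' @param proteome,cds,gff,genome,tpm input file paths.
#' @param progenitors named list of progenitor CDS FASTA paths (one per
#'   species/sub-genome), or NULL to skip orthology.
#' @param progenitor_chromosomes TSV (ortholog_id, species, chromosome).
#' @param chromosome_map TSV (subject_chromosome, query_chromosome,
#'   species).
#' @param motif_file CARE catalogue TSV (default bundled).
#' @param domains_dir directory of domain seed alignments (default
#'   bundled).
#' @param domain_e_max,homology_e_max,homology_bit_min,tandem_identity_min,tandem_max_intervening,pseudogene_threshold,ortholog_e_max,ortholog_bit_min,promoter_length,hsp100_min_distinct
#'   stage thresholds (field-standard defaults).
#' @param sample_groups optional named vector sample id -> group; default
#'   derives the group from the sample-id prefix before the first "_".
#' @param outdir output directory.
#' @param seed integer seed (stages are deterministic; kept for the record).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(proteome, cds, gff, genome, tpm,
                            progenitors = NULL,
                            progenitor_chromosomes = NULL,
                            chromosome_map = NULL,
                            motif_file = system.file(
                              "extdata", "care_motifs.tsv",
                              package = "hspminer"),
                            domains_dir = system.file(
                              "extdata", "domains", package = "hspminer"),
                            domain_e_max = 1e-4, homology_e_max = 1e-4,
                            homology_bit_min = 100,
                            tandem_identity_min = 40,
                            tandem_max_intervening = 5,
                            pseudogene_threshold = 1.0,
                            ortholog_e_max = 1e-10, ortholog_bit_min = 150,
                            promoter_length = 1500,
                            hsp100_min_distinct = 2,
                            sample_groups = NULL,
                            outdir = tempfile("hspminer_run_"), seed = 1) {
  cfg <- list(proteome = proteome, cds = cds, gff = gff, genome = genome,
              tpm = tpm, progenitors = progenitors,
              progenitor_chromosomes = progenitor_chromosomes,
              chromosome_map = chromosome_map, motif_file = motif_file,
              domains_dir = domains_dir, domain_e_max = domain_e_max,
              homology_e_max = homology_e_max,
              homology_bit_min = homology_bit_min,
              tandem_identity_min = tandem_identity_min,
              tandem_max_intervening = tandem_max_intervening,
              pseudogene_threshold = pseudogene_threshold,
              ortholog_e_max = ortholog_e_max,
              ortholog_bit_min = ortholog_bit_min,
              promoter_length = promoter_length,
              hsp100_min_distinct = hsp100_min_distinct,
              sample_groups = sample_groups,
              outdir = outdir, seed = as.integer(seed))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  thr <- c("domain_e_max", "homology_e_max", "homology_bit_min",
           "tandem_identity_min", "tandem_max_intervening",
           "pseudogene_threshold", "ortholog_e_max", "ortholog_bit_min",
           "promoter_length", "hsp100_min_distinct")
  for (t in thr) {
    v <- cfg[[t]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("threshold '%s' must be a positive number", t),
           call. = FALSE)
  }
  for (f in c("proteome", "cds", "gff", "genome", "tpm", "motif_file")) {
    if (!file.exists(cfg[[f]]))
      stop(sprintf("input '%s' not found: %s", f, cfg[[f]]), call. = FALSE)
  }
  if (!is.null(cfg$progenitors)) {
    for (p in unlist(cfg$progenitors))
      if (!file.exists(p)) stop(sprintf("progenitor file not found: %s", p),
                                call. = FALSE)
  }
  invisible(TRUE)
}

#' Run the full identification and characterization pipeline
#'
#' Stages execute in dependency order: identify (domain scan + homology) ->
#' classify/name -> structure -> duplication -> pseudogene -> physchem ->
#' CARE -> expression -> orthology. All stage tables are written to
#' `config$outdir` (atomically: written to a temporary directory and moved
#' in place on success). Any stage failure halts with a stage-named error.
#'
#' @param config a [pipeline_config()].
#' @return An `hsp_run` list: the report plus every stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop(sprintf("stage '%s' failed: %s",
                                              name, conditionMessage(e)),
                                      call. = FALSE))
  }
  res <- list()

  inputs <- stage("load", {
    list(proteome = read_fasta(config$proteome, "aa"),
         cds = read_fasta(config$cds, "nt"),
         models = read_gff3(config$gff),
         genome = read_fasta(config$genome, "nt"),
         tpm = read_tpm_matrix(config$tpm),
         motifs = read_care_motifs(config$motif_file))
  })
  rules <- subfamily_rules(config$hsp100_min_distinct)

  res$identify <- stage("identify", {
    alns <- domain_alignments(config$domains_dir)
    profiles <- domain_profiles(alns)
    domain_hits <- scan_proteome(inputs$proteome, profiles,
                                 e_max = config$domain_e_max)
    seeds <- hsp_seed_proteins(alns)
    homology_all <- homology_search(inputs$proteome, seeds)
    homology_hits <- filter_homology_hits(homology_all,
                                          config$homology_e_max,
                                          config$homology_bit_min)
    candidates <- merge_candidates(domain_hits, homology_hits, rules)
    list(domain_hits = domain_hits, homology_hits = homology_hits,
         candidates = candidates)
  })

  res$classify <- stage("classify", {
    rec <- classify_candidates(res$identify$candidates,
                               res$identify$domain_hits, rules)
    rec <- rec[!is.na(rec$subfamily), , drop = FALSE]
    assign_names(rec, inputs$models)
  })
  records <- res$classify
  fam_ids <- records$gene_id

  res$structure <- stage("structure", {
    sub <- inputs$models
    keep <- sub$genes$gene_id %in% fam_ids
    fam_models <- gene_models(sub$genes[keep, , drop = FALSE],
                              sub$exons[sub$exons$gene_id %in% fam_ids, ,
                                        drop = FALSE])
    structure_stats(fam_models)
  })

  res$duplication <- stage("duplication", {
    td <- find_tandem_duplications(
      fam_ids, inputs$models, inputs$proteome,
      identity_min = config$tandem_identity_min,
      max_intervening = config$tandem_max_intervening)
    ident <- find_identical_duplicates(
      inputs$proteome[fam_ids],
      stats::setNames(records$subfamily, records$gene_id))
    c(td, list(identical = ident))
  })

  res$pseudogenes <- stage("pseudogenes", {
    call_pseudogenes(inputs$tpm, intersect(fam_ids, rownames(inputs$tpm)),
                     threshold = config$pseudogene_threshold)
  })

  res$physchem <- stage("physchem", {
    data.frame(
      gene_id = fam_ids,
      length = nchar(inputs$proteome[fam_ids]),
      molecular_weight = vapply(inputs$proteome[fam_ids],
                                molecular_weight, numeric(1)),
      isoelectric_point = vapply(inputs$proteome[fam_ids],
                                 isoelectric_point, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  })

  res$cares <- stage("cares", {
    counts <- if (!length(fam_ids)) {
      matrix(0L, 0, nrow(inputs$motifs),
             dimnames = list(character(), inputs$motifs$name))
    } else {
      cm <- t(vapply(fam_ids, function(gid) {
        gi <- which(inputs$models$genes$gene_id == gid)
        prom <- extract_promoter(inputs$genome, inputs$models$genes[gi, ],
                                 config$promoter_length)
        scan_cares(as.character(prom), inputs$motifs)
      }, integer(nrow(inputs$motifs))))
      rownames(cm) <- fam_ids
      cm
    }
    list(per_gene = counts,
         summary = summarize_cares(counts, records, inputs$motifs))
  })

  res$expression <- stage("expression", {
    fam_expr <- inputs$tpm[intersect(fam_ids, rownames(inputs$tpm)), ,
                           drop = FALSE]
    groups <- config$sample_groups %||%
      stats::setNames(sub("_.*$", "", colnames(fam_expr)),
                      colnames(fam_expr))
    if (!nrow(fam_expr)) {
      list(scaled = fam_expr, pca = NULL, groups = groups,
           induction = NULL)
    } else {
      scaled <- scale_unit_variance(fam_expr)
      list(scaled = scaled, pca = pca_expression(t(scaled)),
           groups = groups,
           induction = induction_summary(fam_expr, records, groups))
    }
  })

  res$orthology <- if (!length(config$progenitors)) NULL else
    stage("orthology", {
    map <- read_tsv_plain(config$chromosome_map)
    prog_chrom <- read_tsv_plain(config$progenitor_chromosomes)
    subject_chrom <- stats::setNames(records$chromosome, records$gene_id)
    lapply(stats::setNames(nm = names(config$progenitors)), function(sp) {
      prog_cds <- read_fasta(config$progenitors[[sp]], "nt")
      pairs <- find_orthologs(prog_cds, inputs$cds[fam_ids],
                              e_max = config$ortholog_e_max,
                              bit_min = config$ortholog_bit_min)
      species <- paste0("progenitor_", sp)
      qchrom <- stats::setNames(
        as.character(prog_chrom$chromosome[prog_chrom$species == species]),
        prog_chrom$ortholog_id[prog_chrom$species == species])
      spmap <- map[map$species == species, , drop = FALSE]
      sub_ch <- subject_chrom[subject_chrom %in% spmap$subject_chromosome]
      syn <- synteny_fraction(pairs, sub_ch, qchrom, spmap)
      list(pairs = pairs, synteny = syn)
    })
  })

  report <- structure(list(
    version = as.character(utils::packageVersion("hspminer")),
    parameters = config[!(names(config) %in% "sample_groups")],
    input_checksums = tools::md5sum(unlist(
      config[c("proteome", "cds", "gff", "genome", "tpm")])),
    counts = c(
      proteins = length(inputs$proteome),
      candidates = length(res$identify$candidates),
      family_members = nrow(records),
      tandem_pairs = res$duplication$n_events_pairs,
      tandem_arrays = res$duplication$n_events_arrays,
      identical_duplicates = nrow(res$duplication$identical),
      pseudogenes = sum(res$pseudogenes$is_pseudogene),
      care_motifs_seen = res$cares$summary$family_unique_count)),
    class = "hsp_run_report")

  write_run_outputs(res, records, report, config$outdir)
  structure(c(list(report = report, records = records), res),
            class = "hsp_run")
}

write_run_outputs <- function(res, records, report, outdir) {
  tmp <- paste0(outdir, ".tmp")
  unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  write_family_table(records, file.path(tmp, "family_table.tsv"))
  write_tsv_versioned(res$identify$domain_hits,
                      file.path(tmp, "domain_hits.tsv"))
  write_tsv_versioned(res$identify$homology_hits,
                      file.path(tmp, "homology_hits.tsv"))
  write_tsv_versioned(res$structure, file.path(tmp, "gene_structure.tsv"))
  write_tsv_versioned(res$duplication$pairs,
                      file.path(tmp, "tandem_pairs.tsv"))
  write_tsv_versioned(res$duplication$arrays,
                      file.path(tmp, "tandem_arrays.tsv"))
  write_tsv_versioned(res$duplication$identical,
                      file.path(tmp, "identical_duplicates.tsv"))
  write_tsv_versioned(res$pseudogenes, file.path(tmp, "pseudogenes.tsv"))
  write_tsv_versioned(res$physchem, file.path(tmp, "physchem.tsv"))
  write_tpm_matrix(res$cares$per_gene, file.path(tmp, "care_counts.tsv"))
  write_tpm_matrix(res$cares$summary$per_subfamily,
                   file.path(tmp, "care_summary.tsv"), "subfamily")
  write_tpm_matrix(res$expression$scaled,
                   file.path(tmp, "expression_scaled.tsv"))
  if (!is.null(res$expression$pca))
    write_tpm_matrix(res$expression$pca$scores,
                     file.path(tmp, "pca_scores.tsv"), "sample")
  if (!is.null(res$orthology)) {
    for (sp in names(res$orthology)) {
      write_tsv_versioned(res$orthology[[sp]]$pairs,
                          file.path(tmp, sprintf("orthologs_%s.tsv", sp)))
      write_tsv_versioned(res$orthology[[sp]]$synteny,
                          file.path(tmp, sprintf("synteny_%s.tsv", sp)))
    }
  }
  rpt <- data.frame(key = names(report$counts),
                    value = unname(report$counts))
  write_tsv_versioned(rpt, file.path(tmp, "run_report.tsv"))
  unlink(outdir, recursive = TRUE)
  file.rename(tmp, outdir)
  invisible(outdir)
}

#' @export
print.hsp_run_report <- function(x, ...) {
  cat("hspminer run report (v", x$version, ")\n", sep = "")
  for (n in names(x$counts)) cat(sprintf("  %-22s %s\n", n, x$counts[n]))
  invisible(x)
}

#' Mean silhouette of a two-group split in a score space
#'
#' Euclidean silhouette over the supplied coordinates (e.g. the first two
#' principal components); positive values mean the groups separate.
#'
#' @param scores numeric matrix (observations x dims).
#' @param groups group label per row.
#' @return Mean silhouette width.
#' @export
group_silhouette <- function(scores, groups) {
  d <- as.matrix(stats::dist(scores))
  n <- nrow(d)
  s <- vapply(seq_len(n), function(i) {
    own <- groups == groups[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(groups), groups[i]), function(g)
      mean(d[i, groups == g]), numeric(1)))
    if (is.nan(a)) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Generate synthetic data, run the pipeline, and score it against truth
#'
#' The self-validation loop: runs [generate_dataset()], then
#' [run_pipeline()] on the generated files, and compares every stage
#' against the ground truth, reporting precision/recall/accuracy per
#' stage together with the documented acceptance thresholds.
#'
#' @param config a [synthetic_config()].
#' @param dir working directory for the bundle and run output.
#' @return An `hsp_validation` list: `metrics` data frame (stage, metric,
#'   value, threshold, pass), `dataset`, `run`.
#' @export
simulate_and_validate <- function(config = synthetic_config(),
                                  dir = tempfile("hspminer_sim_")) {
  ds <- generate_dataset(config, file.path(dir, "data"))
  pcfg <- pipeline_config(
    proteome = ds$paths[["proteome"]], cds = ds$paths[["cds"]],
    gff = ds$paths[["gff"]], genome = ds$paths[["genome"]],
    tpm = ds$paths[["tpm"]],
    progenitors = {
      sgs <- intersect(paste0("progenitor_", c("A", "B", "D")),
                       names(ds$paths))
      stats::setNames(as.list(ds$paths[sgs]), sub("^progenitor_", "", sgs))
    },
    progenitor_chromosomes = ds$paths[["progenitor_chromosomes"]],
    chromosome_map = ds$paths[["chromosome_map"]],
    outdir = file.path(dir, "run"), seed = config$seed)
  run <- run_pipeline(pcfg)

  truth <- ds$truth$genes
  true_fam <- truth$gene_id[truth$is_family_member]
  pred_fam <- run$records$gene_id
  tp <- intersect(pred_fam, true_fam)
  precision <- if (length(pred_fam)) length(tp) / length(pred_fam) else 1
  recall <- if (length(true_fam)) length(tp) / length(true_fam) else 1

  truth_sub <- stats::setNames(truth$subfamily, truth$gene_id)
  class_acc <- if (length(tp))
    mean(run$records$subfamily[match(tp, run$records$gene_id)] ==
           truth_sub[tp]) else 1

  # pseudogene calls vs truth, over true family members that were found
  ps <- run$pseudogenes
  truth_ps <- stats::setNames(truth$is_pseudogene, truth$gene_id)
  ps_acc <- if (nrow(ps)) mean(ps$is_pseudogene ==
                                 truth_ps[ps$gene_id]) else 1

  # planted tandem arrays recovered with exact membership
  planted <- split(truth$gene_id[!is.na(truth$tandem_array_id)],
                   truth$tandem_array_id[!is.na(truth$tandem_array_id)])
  detected <- lapply(strsplit(run$duplication$arrays$members, ","), sort)
  array_rec <- if (length(planted))
    mean(vapply(planted, function(m)
      any(vapply(detected, identical, logical(1), sort(m))),
      logical(1))) else 1

  # identical-duplicate plantings recovered
  idp <- ds$truth$identical_pairs
  found_pairs <- paste(run$duplication$identical$gene1,
                       run$duplication$identical$gene2)
  ident_rec <- if (nrow(idp))
    mean(paste(idp$gene1, idp$gene2) %in% found_pairs) else 1

  # ortholog pairs recovered as top hits; a subject whose CDS is
  # character-identical to the planted gene's (an identical duplicate) is
  # equivalent, since top hits are score-tied between identical twins
  with_prog <- truth[!is.na(truth$progenitor_ortholog_id) &
                       truth$is_family_member, ]
  all_pairs <- do.call(rbind, lapply(run$orthology, `[[`, "pairs"))
  orth_rec <- if (nrow(with_prog))
    mean(vapply(seq_len(nrow(with_prog)), function(i) {
      hit <- all_pairs$subject_id[
        all_pairs$query_id == with_prog$progenitor_ortholog_id[i]]
      length(hit) == 1 &&
        identical(unname(ds$cds[hit]), unname(ds$cds[with_prog$gene_id[i]]))
    }, logical(1))) else 1

  # CARE counts match planted truth exactly (over found true positives)
  cc <- run$cares$per_gene
  care_ids <- intersect(rownames(cc), rownames(ds$truth$motif_counts))
  care_exact <- if (length(care_ids))
    mean(vapply(care_ids, function(g)
      all(cc[g, colnames(ds$truth$motif_counts)] ==
            ds$truth$motif_counts[g, ]), logical(1))) else 1

  # expression grouping: grain samples vs the rest on PC1-PC2
  sil <- if (is.null(run$expression$pca)) 0 else {
    sc <- run$expression$pca$scores[, 1:2, drop = FALSE]
    grp <- ifelse(run$expression$groups[rownames(sc)] == "grain",
                  "grain", "other")
    group_silhouette(sc, grp)
  }

  metrics <- data.frame(
    stage = c("identify", "identify", "classify", "pseudogenes",
              "duplication", "duplication", "orthology", "cares",
              "expression"),
    metric = c("precision", "recall", "accuracy", "accuracy",
               "array_recovery", "identical_recovery", "top_hit_recovery",
               "count_exactness", "grain_silhouette"),
    value = c(precision, recall, class_acc, ps_acc, array_rec, ident_rec,
              orth_rec, care_exact, sil),
    threshold = c(0.95, 0.95, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 0),
    stringsAsFactors = FALSE)
  metrics$pass <- metrics$value >= metrics$threshold
  structure(list(metrics = metrics, dataset = ds, run = run),
            class = "hsp_validation")
}

#' @export
print.hsp_validation <- function(x, ...) {
  cat("hspminer self-validation\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %-18s %.3f (>= %.2f) %s\n", m$stage[i],
                m$metric[i], m$value[i], m$threshold[i],
                if (m$pass[i]) "PASS" else "FAIL"))
  invisible(x)
}
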