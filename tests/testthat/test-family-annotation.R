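# Evidence merging, sub-family classification, nomenclature and gene
# structure statistics.

dh <- function(protein_id, domain_id, bit = 200) {
  data.frame(protein_id = protein_id, domain_id = domain_id,
             query_start = 1, query_end = 50, raw_score = bit * 2,
             bit_score = bit, e_value = 1e-30, stringsAsFactors = FALSE)
}

test_that("signature domains map to their sub-families", {
  rules <- subfamily_rules()
  expect_equal(assign_subfamily(dh("p", "pfam00011"))$subfamily, "SHSP")
  expect_equal(assign_subfamily(dh("p", "pfam00226"))$subfamily, "HSP40")
  expect_equal(assign_subfamily(dh("p", "pfam00118"))$subfamily, "HSP60")
  expect_equal(assign_subfamily(dh("p", "pfam00012"))$subfamily, "HSP70")

  a90 <- assign_subfamily(rbind(dh("p", "pfam00183"), dh("p", "pfam02518")))
  expect_equal(a90$subfamily, "HSP90")
  expect_length(a90$aux_missing, 0)
  # HSP90 without HATPase_c is still HSP90, with the absence recorded
  a90b <- assign_subfamily(dh("p", "pfam00183"))
  expect_equal(a90b$subfamily, "HSP90")
  expect_identical(a90b$aux_missing, "pfam02518")

  # HSP100 needs two distinct required domains by default
  expect_true(is.na(assign_subfamily(dh("p", "pfam02861"))$subfamily))
  a100 <- assign_subfamily(rbind(dh("p", "pfam02861"), dh("p", "pfam10431")))
  expect_equal(a100$subfamily, "HSP100")
  expect_equal(
    assign_subfamily(dh("p", "pfam02861"),
                     subfamily_rules(hsp100_min_distinct = 1))$subfamily,
    "HSP100")

  expect_true(is.na(assign_subfamily(dh("p", "pfamXXXXX"))$subfamily))
  expect_true(is.na(assign_subfamily(dh("p", "x")[0, ])$subfamily))
})

test_that("chimeric domain content resolves by best bit score, flagged", {
  hits <- rbind(dh("p", "pfam00226", bit = 120),
                dh("p", "pfam02861", bit = 300),
                dh("p", "pfam07724", bit = 280))
  a <- assign_subfamily(hits)
  expect_equal(a$subfamily, "HSP100")
  expect_true(a$conflict)
  hits2 <- rbind(dh("p", "pfam00226", bit = 900),
                 dh("p", "pfam02861", bit = 100),
                 dh("p", "pfam07724", bit = 100))
  expect_equal(assign_subfamily(hits2)$subfamily, "HSP40")
})

test_that("candidate merging unions streams and enforces confirmation", {
  domain_hits <- rbind(dh("gA", "pfam00011"), dh("gB", "pfam00012"))
  homology <- data.frame(query_id = "seed", subject_id = c("gA", "gC"),
                         e_value = 1e-20, bit_score = 300,
                         stringsAsFactors = FALSE)
  cand <- merge_candidates(domain_hits, homology)
  expect_identical(cand, c("gA", "gB"))  # gC lacks a confirmed domain
  expect_identical(merge_candidates(domain_hits[0, ], homology[0, ]),
                   character(0))
})

test_that("names follow chromosome order, prefixes and isoform suffixes", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    chromosome = c("1A", "1A", "2A", "1B", "Un", "1A"),
    start = c(900, 500, 100, 50, 1, 2000),
    end = c(1000, 600, 200, 150, 90, 2100),
    strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  models <- gene_models(genes, exons)
  rec <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4", "g5", "g6"),
    subfamily = c("HSP70", "HSP70", "HSP70", "HSP70", "HSP70", "SHSP"),
    stringsAsFactors = FALSE)
  named <- assign_names(rec, models)
  nm <- setNames(named$assigned_name, named$gene_id)
  # 1A:500 before 1A:900, then 1B, then 2A; unplaced last
  expect_identical(unname(nm[c("g2", "g1", "g4", "g3", "g5")]),
                   c("TaHSP70.1", "TaHSP70.2", "TaHSP70.3", "TaHSP70.4",
                     "TaHSP70.5"))
  expect_identical(unname(nm["g6"]), "TaSHSP1")
  # renaming is stable
  expect_identical(assign_names(rec, models)$assigned_name,
                   named$assigned_name)
  expect_error(assign_names(rbind(rec, rec[1, ]), models), "duplicate")

  # a gene with two mRNAs yields shared-number isoform names
  mrnas <- data.frame(mrna_id = c("g2.1", "g2.2"), gene_id = "g2",
                      start = 500, end = 600, stringsAsFactors = FALSE)
  exons2 <- rbind(
    data.frame(gene_id = "g2", mrna_id = "g2.1", start = 500, end = 600),
    data.frame(gene_id = "g2", mrna_id = "g2.2", start = 500, end = 560),
    data.frame(gene_id = setdiff(genes$gene_id, "g2"), mrna_id = NA,
               start = genes$start[genes$gene_id != "g2"],
               end = genes$end[genes$gene_id != "g2"]))
  models2 <- gene_models(genes, exons2, mrnas)
  named2 <- assign_names(rec, models2)
  iso <- attr(named2, "isoforms")
  expect_identical(iso$isoform_name, c("TaHSP70.1.1", "TaHSP70.1.2"))
})

test_that("per-gene structure uses the longest transcript", {
  genes <- data.frame(gene_id = "g1", chromosome = "1A", start = 100,
                      end = 1000, strand = "+", stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(gene_id = "g1", mrna_id = "m1", start = c(100, 800),
               end = c(300, 1000)),
    data.frame(gene_id = "g1", mrna_id = "m2", start = 100, end = 250))
  models <- gene_models(genes, exons)
  st <- structure_stats(models)
  expect_equal(st$exon_count, 2)  # m1 (402 bp) beats m2 (151 bp)
  expect_equal(st$intron_lengths, "499")
})

test_that("structure statistics follow the intron arithmetic", {
  genes <- data.frame(gene_id = c("a", "b"), chromosome = "1A",
                      start = c(1, 500), end = c(300, 779), strand = "+",
                      stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("a", "a", "b"),
                      start = c(1, 201, 500), end = c(100, 300, 779),
                      stringsAsFactors = FALSE)
  st <- structure_stats(gene_models(genes, exons))
  expect_equal(st$intron_count, c(1, 0))
  expect_equal(st$intron_lengths[1], "100")
  expect_true(st$intronless[2])
  expect_equal(st$gene_length[2], 280)
  expect_error(gene_models(genes, data.frame(
    gene_id = "a", start = c(1, 50), end = c(100, 200))), "overlapping")
})

test_that("distribution summaries match direct group-bys", {
  genes <- data.frame(
    gene_id = paste0("g", 1:5),
    chromosome = c("7D", "7D", "7D", "2A", "Un"),
    start = 1:5 * 1000, end = 1:5 * 1000 + 100, strand = "+",
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                      end = genes$end, stringsAsFactors = FALSE)
  rec <- assign_names(
    data.frame(gene_id = genes$gene_id,
               subfamily = c("SHSP", "SHSP", "HSP70", "HSP70", "HSP70"),
               stringsAsFactors = FALSE),
    gene_models(genes, exons))
  ds <- distribution_summary(rec)
  expect_equal(as.numeric(ds$per_chromosome[c("7D", "2A")]), c(3, 1))
  expect_equal(sum(ds$per_subgenome), sum(ds$per_chromosome))
  expect_equal(ds$n_unplaced, 1)

  # synthetic bundle counts equal truth-table group-bys
  v <- get_small_validation()
  tg <- v$dataset$truth$genes
  fam_truth <- tg[tg$is_family_member, ]
  d2 <- distribution_summary(v$run$records)
  expect_equal(as.vector(d2$per_subfamily[sort(unique(fam_truth$subfamily))]),
               as.vector(table(fam_truth$subfamily)))
  placed <- table(fam_truth$chromosome)
  expect_equal(as.vector(d2$per_chromosome[names(placed)]),
               as.vector(placed))
})
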