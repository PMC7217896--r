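# Tandem-duplication rule (with exact boundary fixtures), identical
# duplicates, top-hit orthology and synteny fractions.

# two proteins whose optimal local alignment is the full ungapped overlap
# with exactly 40% identity: 4 identical W (11 each) plus 6 positively
# scoring K/R mismatches (+2 each); every sub-alignment scores less
p40_a <- "WWWWKKKKKK"
p40_b <- "WWWWRRRRRR"

test_that("the 40% identity boundary is strict", {
  aln <- smith_waterman(p40_a, p40_b)
  expect_equal(aln$identity_pct, 40)
  models <- toy_models(c("1A", "1A"), c(1000, 3000), "+")
  prot <- c(t01 = p40_a, t02 = p40_b)
  td <- find_tandem_duplications(c("t01", "t02"), models, prot)
  expect_equal(nrow(td$pairs), 0)
  # one more identical residue tips it over 40%
  prot2 <- c(t01 = "WWWWWKKKKK", t02 = "WWWWWRRRRR")
  td2 <- find_tandem_duplications(c("t01", "t02"), models, prot2)
  expect_equal(nrow(td2$pairs), 1)
  expect_equal(td2$pairs$identity_pct, 50)
})

test_that("the intervening-gene boundary is strict at five", {
  prot <- c(t01 = "MKWWWWHHHH", t07 = "MKWWWWHHHH")
  build <- function(n_between) {
    starts <- c(1000, 1000 + 500 * seq_len(n_between), 1000 + 500 * (n_between + 1))
    ids <- c("t01", sprintf("d%02d", seq_len(n_between)), "t07")
    genes <- data.frame(gene_id = ids, chromosome = "1A", start = starts,
                        end = starts + 300, strand = "+",
                        stringsAsFactors = FALSE)
    exons <- data.frame(gene_id = ids, start = starts, end = starts + 300,
                        stringsAsFactors = FALSE)
    gene_models(genes, exons)
  }
  td5 <- find_tandem_duplications(c("t01", "t07"), build(5), prot)
  expect_equal(nrow(td5$pairs), 0)
  td4 <- find_tandem_duplications(c("t01", "t07"), build(4), prot)
  expect_equal(nrow(td4$pairs), 1)
  expect_equal(td4$pairs$intervening, 4)
  # opposite strands never pair
  m <- build(0)
  m$genes$strand <- c("+", "-")
  expect_equal(nrow(find_tandem_duplications(c("t01", "t07"), m, prot)$pairs), 0)
})

test_that("missing family protein is an error naming the gene", {
  models <- toy_models(c("1A", "1A"), c(1000, 3000))
  expect_error(find_tandem_duplications(c("t01", "t02"), models,
                                        c(t01 = "MKWW")), "t02")
})

test_that("tandem detection equals the brute-force all-pairs oracle", {
  ds <- get_small_dataset()
  fam <- ds$truth$genes$gene_id[ds$truth$genes$is_family_member]
  td <- find_tandem_duplications(fam, ds$models, ds$proteome)
  got <- sort(paste(td$pairs$gene1, td$pairs$gene2))
  want <- oracle_tandem_pairs(fam, ds$models$genes, ds$proteome)
  expect_identical(got, want)

  # planted arrays recovered as connected components with exact membership
  tg <- ds$truth$genes
  planted <- split(tg$gene_id[!is.na(tg$tandem_array_id)],
                   tg$tandem_array_id[!is.na(tg$tandem_array_id)])
  detected <- lapply(strsplit(td$arrays$members, ","), sort)
  for (p in planted)
    expect_true(any(vapply(detected, identical, logical(1), sort(p))))
  expect_equal(length(detected), length(planted))
})

test_that("identical duplicates need exact equality, not position", {
  set.seed(51)
  base <- rand_seq(500)
  one_sub <- mutate_sequence(base, 0)  # same
  substr(one_sub, 250, 250) <- if (substr(base, 250, 250) == "A") "C" else "A"
  prot <- c(x1 = base, x2 = base, x3 = one_sub)
  fams <- c(x1 = "SHSP", x2 = "SHSP", x3 = "SHSP")
  idp <- find_identical_duplicates(prot, fams)
  expect_equal(nrow(idp), 1)
  expect_identical(c(idp$gene1, idp$gene2), c("x1", "x2"))

  # same sequences in different sub-families do not pair
  idp2 <- find_identical_duplicates(prot, c(x1 = "SHSP", x2 = "HSP70",
                                            x3 = "SHSP"))
  expect_equal(nrow(idp2), 0)

  # identical duplicates on different chromosomes are not tandem pairs:
  # the two detectors are independent
  models <- toy_models(c("1A", "2A"), c(1000, 1000))
  td <- find_tandem_duplications(c("t01", "t02"), models,
                                 c(t01 = base, t02 = base))
  expect_equal(nrow(td$pairs), 0)
  idp3 <- find_identical_duplicates(c(t01 = base, t02 = base),
                                    c(t01 = "SHSP", t02 = "SHSP"))
  expect_equal(nrow(idp3), 1)
})

test_that("ortholog search reports thresholded best bits with fixed ties", {
  set.seed(52)
  cds <- vapply(1:4, function(i) rand_seq(600, NT4), character(1))
  names(cds) <- paste0("w", 1:4)
  q <- c(q1 = mutate_sequence(cds[["w2"]], 0.05, NT4))
  pairs <- find_orthologs(q, cds)
  expect_equal(nrow(pairs), 1)
  expect_identical(pairs$subject_id, "w2")
  expect_gt(pairs$identity_pct, 90)

  # identical CDS in the subject set is a 100%-identity top hit
  pid <- find_orthologs(c(qq = cds[["w1"]]), cds)
  expect_identical(pid$subject_id, "w1")
  expect_equal(pid$identity_pct, 100)

  # below the bit floor nothing is reported (short query cannot reach 150)
  short <- c(qs = substr(cds[["w1"]], 1, 80))
  expect_equal(nrow(find_orthologs(short, cds)), 0)

  # exact score ties resolve to the lexically smaller subject
  twin <- c(zb = cds[["w3"]], za = cds[["w3"]])
  tie <- find_orthologs(c(qt = cds[["w3"]]), twin)
  expect_identical(tie$subject_id, "za")
})

test_that("synteny fractions count corresponding chromosomes", {
  subject_chrom <- setNames(rep("1A", 10), paste0("g", 1:10))
  query_chrom <- setNames(c(rep("1", 8), rep("3", 2)), paste0("pg", 1:10))
  pairs <- data.frame(query_id = paste0("pg", 1:10),
                      subject_id = paste0("g", 1:10),
                      stringsAsFactors = FALSE)
  map <- data.frame(subject_chromosome = "1A", query_chromosome = "1",
                    stringsAsFactors = FALSE)
  syn <- synteny_fraction(pairs, subject_chrom, query_chrom, map)
  expect_equal(syn$fraction, 0.8)  # 2 of 10 translocated

  syn1 <- synteny_fraction(pairs, subject_chrom,
                           setNames(rep("1", 10), paste0("pg", 1:10)), map)
  expect_equal(syn1$fraction, 1.0)
  syn0 <- synteny_fraction(pairs[0, ], subject_chrom, query_chrom, map)
  expect_equal(syn0$fraction, 0.0)
  # chromosome missing from the map: counted non-syntenic, with a message
  expect_message(
    syn_na <- synteny_fraction(pairs, subject_chrom, query_chrom,
                               data.frame(subject_chromosome = "9X",
                                          query_chromosome = "9")),
    "absent")
  expect_equal(syn_na$fraction, 0)
})
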