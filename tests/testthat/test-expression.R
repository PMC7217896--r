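# Pseudogene calling, unit-variance scaling, PCA and induction summaries.

test_that("pseudogene calls apply the strict TPM-sum rule", {
  m <- matrix(c(0.33, 0.33, 0.33,   # 0.99 -> pseudogene
                0.50, 0.25, 0.25,   # 1.00 exactly -> not
                0, 0, 0,            # all-zero -> pseudogene
                5, 0, 0), 4, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("s1", "s2", "s3")))
  calls <- call_pseudogenes(m)
  expect_identical(calls$is_pseudogene, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(calls$tpm_sum, c(0.99, 1.00, 0, 5))
  expect_error(call_pseudogenes(m, genes = c("a", "zz")), "zz")
  # non-strict mode includes the boundary
  expect_true(call_pseudogenes(m, genes = "b", strict = FALSE)$is_pseudogene)
  # deterministic and equal to the generator's truth
  ds <- get_small_dataset()
  fam <- ds$truth$genes$gene_id[ds$truth$genes$is_family_member]
  calls2 <- call_pseudogenes(ds$tpm, fam)
  truth <- setNames(ds$truth$genes$is_pseudogene, ds$truth$genes$gene_id)
  expect_identical(calls2$is_pseudogene, unname(truth[fam]))
})

test_that("unit-variance scaling uses the n-1 convention", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("a", "b", "c")))
  s <- scale_unit_variance(m)
  expect_equal(unname(s["r1", ]), c(-1, 0, 1))
  expect_equal(unname(s["r2", ]), c(0, 0, 0))
  expect_identical(attr(s, "constant_rows"), "r2")
  expect_error(scale_unit_variance(m[, 1, drop = FALSE]), "2 columns")
  # population-sd variant scales by sqrt((n-1)/n) relative to sample sd
  sp <- scale_unit_variance(m, sd_type = "population")
  expect_equal(unname(sp["r1", ]), c(-1, 0, 1) * sqrt(3 / 2))

  set.seed(61)
  big <- matrix(rlnorm(300), 30, 10)
  sb <- scale_unit_variance(big)
  expect_true(all(abs(rowMeans(sb)) < 1e-12))
  expect_true(all(abs(apply(sb, 1, sd) - 1) < 1e-12))
})

test_that("PCA satisfies variance, duplication and invariance properties", {
  set.seed(62)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("s", 1:6), paste0("f", 1:10)))
  p <- pca_expression(m)
  expect_equal(sum(p$variance_explained), 100)

  # duplicated samples land on identical score coordinates
  m2 <- rbind(m, s7 = m[1, ])
  p2 <- pca_expression(m2)
  expect_equal(p2$scores["s7", ], p2$scores["s1", ])

  # rank-1 data puts all variance on PC1
  r1 <- outer(c(1, 2, 3, 4), rnorm(10))
  rownames(r1) <- paste0("s", 1:4)
  expect_equal(pca_expression(r1)$variance_explained[1], 100)

  # sample reordering permutes scores but changes nothing else
  ord <- c(4, 2, 6, 1, 3, 5)
  p3 <- pca_expression(m[ord, ])
  expect_equal(p3$scores, p$scores[ord, ], tolerance = 1e-6)
  expect_equal(p3$variance_explained, p$variance_explained)

  expect_error(pca_expression(matrix(0, 3, 3)), "all-zero")
  expect_error(pca_expression(m[1, , drop = FALSE]), "2 samples")
})

test_that("group structure in expression yields separable PC scores", {
  set.seed(63)
  # 20 genes x 8 samples; genes induced 6-fold in the grain-like group
  base <- matrix(rlnorm(160, 2, 0.3), 20, 8)
  base[1:10, 1:4] <- base[1:10, 1:4] * 6
  rownames(base) <- paste0("g", 1:20)
  colnames(base) <- c(paste0("grain_r", 1:4), paste0("leaf_r", 1:4))
  sc <- pca_expression(t(scale_unit_variance(base)))$scores[, 1:2]
  sil <- group_silhouette(sc, rep(c("grain", "other"), each = 4))
  expect_gt(sil, 0)
})

test_that("induction summaries recover planted group effects", {
  set.seed(64)
  m <- matrix(rlnorm(120, 1, 0.2), 10, 12)
  rownames(m) <- paste0("g", 1:10)
  colnames(m) <- paste0(rep(c("grain", "leaf", "root"), each = 4), "_r",
                        1:4)
  groups <- setNames(rep(c("grain", "leaf", "root"), each = 4),
                     colnames(m))
  m[1:5, 1:4] <- m[1:5, 1:4] * 10  # sub-family X induced in grain only
  rec <- data.frame(gene_id = paste0("g", 1:10),
                    subfamily = rep(c("X", "Y"), each = 5),
                    stringsAsFactors = FALSE)
  im <- induction_summary(m, rec, groups)
  expect_equal(names(which.max(im["X", ])), "grain")

  # balanced null data: group means hover near zero
  null_m <- matrix(rlnorm(1200, 1, 0.2), 100, 12,
                   dimnames = list(paste0("n", 1:100), colnames(m)))
  rec_null <- data.frame(gene_id = rownames(null_m), subfamily = "Z",
                         stringsAsFactors = FALSE)
  im0 <- induction_summary(null_m, rec_null, groups)
  expect_true(all(abs(im0) < 0.5))

  # sub-family absent from the matrix is dropped with a notice
  rec2 <- rbind(rec, data.frame(gene_id = "ghost", subfamily = "W"))
  expect_message(im2 <- induction_summary(m, rec2, groups), "W")
  expect_false("W" %in% rownames(im2))
  expect_error(induction_summary(m, rec, groups[-1]), "without group")
})
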