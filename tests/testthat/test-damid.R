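toy_table <- function(ctrl, mut, fdr = 0.01, n_gatc = 5) {
  n <- length(ctrl)
  tibble::tibble(gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr2L",
                 start = seq_len(n) * 1e4, end = seq_len(n) * 1e4 + 2e3,
                 occ_ctrl_rep1 = ctrl, occ_ctrl_rep2 = ctrl,
                 occ_ctrl_rep3 = ctrl,
                 occ_mut_rep1 = mut, occ_mut_rep2 = mut, occ_mut_rep3 = mut,
                 fdr = fdr, n_gatc = n_gatc)
}

test_that("gene filters use strict FDR and GATC cut-offs", {
  tbl <- toy_table(rnorm(4), rnorm(4))
  tbl$fdr <- c(0.049, 0.05, 0.01, 0.2)
  tbl$n_gatc <- c(5L, 5L, 1L, 5L)
  out <- filter_genes(tbl)
  expect_identical(out$gene_id, "g01")  # fdr = 0.05 and gatc = 1 both fail
  expect_identical(nrow(filter_genes(tbl[0, ])), 0L)
  expect_warning(filter_genes(dplyr::mutate(tbl, fdr = 1)), "no genes")
})

test_that("PCA z-scores match a closed-form eigen oracle", {
  withr::with_seed(8, {
    x <- rnorm(10)
    y <- 0.8 * x + rnorm(10, sd = 0.3)
  })
  tbl <- toy_table(x, y)
  h <- pca_regression_hits(tbl)

  # oracle: explicit 2x2 eigen-decomposition of the covariance
  pts <- cbind(rowMeans(tbl[paste0("occ_ctrl_rep", 1:3)]),
               rowMeans(tbl[paste0("occ_mut_rep", 1:3)]))
  cv <- stats::cov(pts)
  ev <- eigen(cv)
  v2 <- ev$vectors[, 2]
  if (v2[2] < 0) v2 <- -v2
  s <- sweep(pts, 2, colMeans(pts)) %*% v2
  z_ref <- drop(s) / sd(s)
  expect_equal(h$z_pca, z_ref, tolerance = 1e-9)

  # swapping conditions negates the scores
  swapped <- toy_table(y, x)
  h2 <- pca_regression_hits(swapped)
  expect_equal(h2$z_pca, -h$z_pca, tolerance = 1e-9)
})

test_that("a single displaced gene is the only significant call", {
  x <- seq(-2, 2, length.out = 9)
  tbl <- toy_table(c(x, 0), c(x, 2.5))  # last gene far off the diagonal
  h <- pca_regression_hits(tbl)
  expect_identical(which(h$significant), 10L)
  expect_identical(h$direction[10], "increased")
  expect_true(all(abs(h$z_pca[1:9]) < 1.96))

  # direction flips when the displacement is towards control
  h2 <- pca_regression_hits(toy_table(c(x, 2.5), c(x, 0)))
  expect_identical(h2$direction[10], "decreased")

  # hit calling is invariant to gene order
  perm <- sample(10)
  h3 <- pca_regression_hits(toy_table(c(x, 0)[perm], c(x, 2.5)[perm]))
  expect_equal(h3$z_pca, h$z_pca[perm], tolerance = 1e-9)
})

test_that("degenerate clouds and tiny tables are rejected", {
  expect_error(pca_regression_hits(toy_table(rnorm(2), rnorm(2))),
               "at least 3")
  expect_error(pca_regression_hits(toy_table(rep(1, 5), rep(2, 5))),
               "degenerate|single line")
  expect_error(pca_regression_hits(toy_table(1:5, 1:5 * 2)), "single line")
})

test_that("significance combines z, FDR and GATC criteria", {
  x <- seq(-2, 2, length.out = 9)
  tbl <- toy_table(c(x, 0), c(x, 2.5))
  tbl$fdr[10] <- 0.2      # outlier fails the FDR criterion
  h <- pca_regression_hits(tbl)
  expect_false(any(h$significant))
  tbl$fdr[10] <- 0.01
  tbl$n_gatc[10] <- 1L    # now fails the GATC criterion
  expect_false(any(pca_regression_hits(tbl)$significant))
})

test_that("group overlap percentages cover the documented conventions", {
  expect_identical(group_overlap(c("a", "b"), c("c", "d")), 0)
  expect_identical(group_overlap(c("a", "b"), c("a", "b")), 100)
  expect_equal(group_overlap(c("a", "b", "c"), c("c", "d")), 25)
  expect_equal(group_overlap(c("a", "b", "c"), c("c", "d"),
                             denominator = "min"), 50)
  expect_identical(group_overlap(character(), character()), 0)
})

test_that("gap-statistic clustering finds the right number of blobs", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(90, 0, 0.5), ncol = 3),
               matrix(rnorm(90, 6, 0.5), ncol = 3),
               matrix(rnorm(90, -6, 0.5), ncol = 3))
  })
  truth <- rep(1:3, each = 30)
  cl <- cluster_fold_changes(x, seed = 1)
  expect_identical(cl$k, 3L)
  # labels match the blobs up to permutation, and across seeds
  expect_true(same_partition(cl$labels$cluster, truth))
  cl2 <- cluster_fold_changes(x, seed = 99)
  expect_true(same_partition(cl2$labels$cluster, cl$labels$cluster))

  withr::with_seed(5, one <- matrix(rnorm(120), ncol = 3))
  expect_identical(cluster_fold_changes(one, seed = 1)$k, 1L)
})

test_that("missing fold changes impute to zero and empty rows drop", {
  withr::with_seed(3, {
    x <- rbind(matrix(rnorm(60, 0, 0.4), ncol = 3),
               matrix(rnorm(60, 5, 0.4), ncol = 3))
  })
  x[1, 2] <- NA                       # partial missingness is imputed
  x <- rbind(x, c(NA, NA, NA))        # all-missing row is dropped
  expect_warning(cl <- cluster_fold_changes(x, k_max = 3, seed = 1),
                 "all-missing")
  expect_identical(nrow(cl$labels), 40L)
  expect_identical(cl$k, 2L)
})
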