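test_that("proximal gene counting follows the interval-gap definition", {
  genes <- tibble::tibble(chrom = c("chr2L", "chr2L"),
                          start = c(0, 7000), end = c(2000, 9000))
  expect_identical(count_proximal_genes(genes, window = 10000), 2L)
  expect_identical(count_proximal_genes(genes, window = 5000), 0L)
  # gap exactly at the window is not "near" (strict <)
  genes$start[2] <- 12000; genes$end[2] <- 14000
  expect_identical(count_proximal_genes(genes, window = 10000), 0L)
  # different chromosomes never pair
  genes$chrom[2] <- "chr3R"
  genes$start[2] <- 2500
  expect_identical(count_proximal_genes(genes, window = 10000), 0L)
  # midpoint metric
  mg <- tibble::tibble(chrom = "chr2L", start = c(0, 8000),
                       end = c(2000, 10000))
  expect_identical(count_proximal_genes(mg, 10000, distance = "midpoint"), 2L)
  expect_identical(count_proximal_genes(mg, 7000, distance = "midpoint"), 0L)
})

test_that("gap distances agree with the interval-tree oracle", {
  for (seed in 1:4) {
    ann <- gen_annotation(c(chrA = 2e6, chrB = 1e6), 150, seed = seed)
    pick <- withr::with_seed(seed, sample.int(150, 40))
    sub <- ann[pick, ]
    fast <- chromatether:::nearest_neighbor_distance(sub$chrom, sub$start,
                                                     sub$end)
    ir_count <- function(sub, w) {
      tot <- 0L
      for (ch in unique(sub$chrom)) {
        s <- sub[sub$chrom == ch, ]
        if (nrow(s) < 2) next
        ir <- IRanges::IRanges(s$start + 1L, s$end)
        n <- length(ir)
        pairs <- expand.grid(i = seq_len(n), j = seq_len(n))
        pairs <- pairs[pairs$i != pairs$j, ]
        d <- IRanges::distance(ir[pairs$i], ir[pairs$j])
        nearest <- tapply(d, pairs$i, min)
        tot <- tot + sum(nearest < w)
      }
      tot
    }
    for (w in c(5e3, 2e4, 1e5)) {
      expect_identical(count_proximal_genes(sub, w),
                       ir_count(sub, w))
      expect_identical(sum(fast < w), ir_count(sub, w))
    }
  }
})

test_that("Monte-Carlo proximity p-values use the add-one estimator", {
  ann <- gen_annotation(c(chr2L = 5e6, chr2R = 5e6, chr3L = 5e6,
                          chr3R = 5e6), 200, seed = 1)
  hits <- ann$gene_id[seq(1, 40, by = 2)]
  pt <- proximity_mc_test(hits, ann, nruns = 200, seed = 4)
  nge <- sum(pt$null_counts >= pt$observed_count)
  expect_identical(pt$p_value, (nge + 1) / 201)
  expect_gte(pt$p_value, 1 / 201)
  expect_lte(pt$p_value, 1)
  expect_identical(length(pt$null_counts), 200L)
  # reproducible given the seed
  pt2 <- proximity_mc_test(hits, ann, nruns = 200, seed = 4)
  expect_identical(pt2$null_counts, pt$null_counts)

  expect_error(proximity_mc_test("nope", ann), "annotation genes")
})

test_that("hits on distinct chromosomes give observed 0 and p of 1", {
  ann <- tibble::tibble(chrom = c("chr2L", "chr2R", "chr3L", "chr3R"),
                        start = 1e5, end = 1e5 + 2000,
                        gene_id = paste0("g", 1:4))
  pt <- proximity_mc_test(paste0("g", 1:4), ann, nruns = 50, seed = 1)
  expect_identical(pt$observed_count, 0L)
  expect_identical(pt$p_value, 1)
})

test_that("clustered synthetic truth is detected as significant", {
  spec <- synth_damid_spec(clustering = "clustered", n_true_hits = 40,
                           n_genes = 2000)
  d <- gen_damid_table(spec, seed = 11)
  ann <- d$table[c("chrom", "start", "end", "gene_id")]
  hits <- d$truth$gene_id[d$truth$is_hit]
  pt <- proximity_mc_test(hits, ann, nruns = 1000, seed = 2)
  expect_lt(pt$p_value, 0.05)
  expect_gt(pt$observed_count, pt$null_median)
})

test_that("null proximity p-values are calibrated on their support", {
  ann <- gen_annotation(c(chr2L = 3e6, chr2R = 3e6, chr3L = 3e6,
                          chr3R = 3e6), 300, seed = 5)
  ps <- vapply(1:200, function(i) {
    hits <- withr::with_seed(1000 + i, sample(ann$gene_id, 25))
    proximity_mc_test(hits, ann, nruns = 99, seed = i)$p_value
  }, numeric(1))
  # validity: P(p <= a) should not exceed a (within binomial noise)
  for (a in c(0.05, 0.25, 0.5)) {
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / 200))
  }
  # and the p-values are not degenerate
  expect_gt(mean(ps <= 0.5), 0.5 - 3 * sqrt(0.25 / 200) - 0.1)
})
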