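test_that("bead count arithmetic rounds the genome onto the lattice", {
  expect_identical(compute_bead_count(176.2e6, 5000), 35240L)
  expect_identical(compute_bead_count(5000, 5000), 1L)
  expect_identical(compute_bead_count(123456, 5000), 25L)  # 24.69 rounds up
  expect_error(compute_bead_count(0, 5000), "positive")
  expect_error(compute_bead_count(1e6, -1), "positive")
})

test_that("genome partition yields exact compartment counts and chains", {
  spec <- genome_spec()
  beads <- partition_genome(spec, n_beads = 35240)
  expect_identical(sum(beads$compartment == "PCH"), 10572L)
  expect_identical(nrow(beads), 35240L)
  expect_identical(length(unique(beads$chromosome)), 4L)

  # equal chains when divisible
  b40 <- partition_genome(spec, n_beads = 40)
  expect_true(all(table(b40$chromosome) == 10))

  # frac_pch = 0 gives all-EU
  s0 <- genome_spec(frac_euchromatin = 1, frac_pch = 0)
  expect_true(all(partition_genome(s0, 100)$compartment == "EU"))

  # PCH blocks are one contiguous run per chromosome
  for (ch in 1:4) {
    sub <- beads[beads$chromosome == ch, ]
    r <- rle(sub$compartment == "PCH")
    expect_identical(sum(r$values), 1L)
  }
})

test_that("invalid genome specifications are rejected", {
  expect_error(genome_spec(frac_euchromatin = 0.6, frac_pch = 0.3), "equal 1")
  expect_error(genome_spec(h3k27me3_target_coverage = 1.2), "\\[0, 1\\)")
  expect_error(genome_spec(mean_patch_len_beads = 0.5), ">= 1")
  expect_error(partition_genome(genome_spec(), n_beads = 2),
               "n_chromosomes")
})

test_that("patch generation hits its coverage target and is reproducible", {
  spec <- genome_spec()
  beads <- partition_genome(spec, n_beads = 20000)
  a <- generate_h3k27me3_patches(beads, spec, seed = 7)
  b <- generate_h3k27me3_patches(beads, spec, seed = 7)
  expect_identical(a$h3k27me3, b$h3k27me3)
  cov <- mean(a$h3k27me3)
  expect_gte(cov, 0.40)
  expect_lt(cov, 0.41)

  # bookkeeping reconstructs the flag vector exactly
  p <- attr(a, "patches")
  flags <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(p))) flags[p$start[i] + seq_len(p$length[i]) - 1] <- TRUE
  expect_identical(flags, a$h3k27me3)

  # patches never straddle chromosome boundaries
  expect_true(all(a$chromosome[p$start] == a$chromosome[p$start + p$length - 1]))

  # zero target leaves no flags
  s0 <- genome_spec(h3k27me3_target_coverage = 0)
  expect_false(any(generate_h3k27me3_patches(beads, s0, seed = 1)$h3k27me3))

  # near-saturating targets are refused
  s95 <- genome_spec(h3k27me3_target_coverage = 0.96)
  expect_error(generate_h3k27me3_patches(beads, s95, seed = 1),
               "terminating")
  expect_error(generate_h3k27me3_patches(a, spec, seed = 1), "already carry")
})

test_that("per-compartment mode tracks its separate coverage targets", {
  spec <- genome_spec(coverage_mode = "per_compartment")
  beads <- partition_genome(spec, n_beads = 20000)
  b <- generate_h3k27me3_patches(beads, spec, seed = 3)
  st <- patch_statistics(b)
  expect_equal(st$coverage_eu, 0.22, tolerance = 0.01)
  expect_equal(st$coverage_pch, 0.775, tolerance = 0.01)
  # compartment coverages compose to slightly below the global 40% target
  expect_equal(st$coverage, 0.7 * 0.22 + 0.3 * 0.775, tolerance = 0.01)
})

test_that("patch statistics summarise flag runs", {
  beads <- tibble::tibble(bead_index = 1:4, chromosome = 1L,
                          compartment = c("EU", "EU", "PCH", "PCH"),
                          h3k27me3 = c(TRUE, TRUE, FALSE, TRUE))
  st <- patch_statistics(beads)
  expect_identical(st$n_patches, 2L)
  expect_equal(st$mean_len, 1.5)
  expect_equal(st$coverage, 0.75)
  expect_equal(st$coverage_eu, 1)
  expect_equal(st$coverage_pch, 0.5)

  none <- patch_statistics(dplyr::mutate(beads, h3k27me3 = FALSE))
  expect_identical(none$n_patches, 0L)
  expect_true(is.na(none$mean_len))
  expect_identical(none$coverage, 0)
})

test_that("coverage and patch length converge over many seeds", {
  spec <- genome_spec()
  beads <- partition_genome(spec, n_beads = 20000)
  covs <- numeric(50)
  lens <- c()
  for (s in 1:50) {
    b <- generate_h3k27me3_patches(beads, spec, seed = s)
    covs[s] <- mean(b$h3k27me3)
    lens <- c(lens, attr(b, "patches")$length)
  }
  expect_gte(mean(covs), 0.40)
  expect_lte(mean(covs), 0.405)
  expect_lt(abs(mean(lens) - 17), 1)
})
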