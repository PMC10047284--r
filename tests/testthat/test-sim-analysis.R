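make_h3k_state <- function(pos, bonds = NULL, radius = 50) {
  n <- nrow(pos)
  beads <- tibble::tibble(bead_index = seq_len(n), chromosome = 1L,
                          compartment = "EU", h3k27me3 = TRUE)
  sim_state(pos, beads, lamina = matrix(0, 1, 3), radius = radius,
            bonds = bonds)
}

test_that("contact clusters decompose as expected on simple geometries", {
  st <- make_h3k_state(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.8, 0)))
  cs <- identify_clusters(st, 1.5, nucleoplasmic_only = FALSE)
  expect_identical(cs$n_clusters, 1L)
  expect_identical(cs$cluster_sizes, 3L)

  far <- make_h3k_state(cbind(seq(0, 90, by = 10), 0, 0), radius = 100)
  cs2 <- identify_clusters(far, 1.5, nucleoplasmic_only = FALSE)
  expect_identical(cs2$n_clusters, 10L)
  expect_true(all(cs2$cluster_sizes == 1L))
})

test_that("cluster decomposition matches a brute-force oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      pos <- matrix(runif(3 * 60, -5, 5), ncol = 3)
    })
    st <- make_h3k_state(pos)
    cs <- identify_clusters(st, 1.5, nucleoplasmic_only = FALSE)
    lab <- cs$membership$cluster
    ref <- oracle_components(pos, 1.5)
    expect_true(same_partition(lab, ref))
    # a partition: every bead in exactly one cluster
    expect_identical(sum(cs$cluster_sizes), nrow(pos))
  }
})

test_that("nucleoplasm filters drop lamina-attached or peripheral clusters", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0),      # interior pair
               c(48, 0, 0), c(48.9, 0, 0))  # peripheral pair (R = 50)
  st <- make_h3k_state(pos, bonds = c(0L, 0L, 1L, 0L))
  cs <- identify_clusters(st, 1.5, nucleoplasmic_only = TRUE,
                          method = "unbonded")
  expect_identical(cs$n_clusters, 1L)
  expect_identical(cs$cluster_sizes, 2L)

  cs_int <- identify_clusters(st, 1.5, nucleoplasmic_only = TRUE,
                              method = "interior", interior_margin = 2)
  expect_identical(cs_int$n_clusters, 1L)

  cs_all <- identify_clusters(st, 1.5, nucleoplasmic_only = FALSE)
  expect_identical(cs_all$n_clusters, 2L)
})

test_that("radial density is normalised, rotation-invariant and localises mass", {
  withr::with_seed(1, {
    u <- matrix(rnorm(3000 * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2)) * runif(3000)^(1 / 3) * 10
  })
  st <- make_h3k_state(u, radius = 10)
  prof <- radial_density(st, n_shells = 5)
  # volume-weighted mean is exactly 1
  vol <- (prof$r_hi^3 - prof$r_lo^3)
  expect_equal(sum(prof$density * vol), 1, tolerance = 1e-6)
  # uniform points give flat profiles (3 standard errors)
  se <- 3 / sqrt(prof$count)
  expect_true(all(abs(prof$density - 1) < 3 * pmax(se, 0.05) + 0.15))

  # rotation invariance
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  st_rot <- make_h3k_state(u %*% rot, radius = 10)
  expect_equal(radial_density(st_rot, 5)$density, prof$density)

  # all mass at the centre
  st_c <- make_h3k_state(matrix(rnorm(300, 0, 0.2), ncol = 3), radius = 10)
  pc <- radial_density(st_c, 5)
  expect_gt(pc$density[1], 0)
  expect_true(all(pc$density[4:5] == 0))
  expect_error(radial_density(st_c, n_shells = 1), "n_shells")
})

fake_traj <- function(sizes_per_frame, radius = 200) {
  # one compact cluster of the requested size plus spaced-out singletons
  n <- max(sizes_per_frame) + 3
  frames <- lapply(sizes_per_frame, function(k) {
    cluster <- cbind(seq_len(k) * 0.9, 0, 0)
    singles <- cbind(-100, seq_len(n - k) * 5, 0)
    rbind(cluster, singles)
  })
  beads <- tibble::tibble(bead_index = seq_len(n), chromosome = 1L,
                          compartment = "EU", h3k27me3 = TRUE)
  structure(list(frames = frames,
                 bonds = lapply(frames, function(f) integer(nrow(f))),
                 beads = beads, lamina = matrix(0, 1, 3), radius = radius,
                 config = sim_config(), stride = 1L,
                 steps = length(frames) - 1L, seed = 1),
            class = "chromatin_trajectory")
}

test_that("tether comparison detects shifted cluster sizes by rank test", {
  withr::with_seed(4, {
    a <- fake_traj(pmax(2, rpois(40, 4)))
    b <- fake_traj(pmax(2, rpois(40, 4)) + 10)
  })
  cmp <- compare_tether_strengths(a, b, burn_in_fraction = 0.5)
  expect_identical(cmp$direction, "B larger")
  expect_lt(cmp$p_value, 0.01)
  out <- tidy(cmp)
  expect_identical(out$direction, "B larger")

  same <- compare_tether_strengths(a, a, burn_in_fraction = 0.5)
  expect_gte(same$p_value, 0.5)
  expect_error(compare_tether_strengths(fake_traj(c(3, 3)), a,
                                        burn_in_fraction = 0.9),
               "insufficient")
})
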