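test_that("confinement radius matches the volume-fraction closed form", {
  R <- confinement_radius(35240, 0.15)
  expect_equal(R, (35240 / 1.2)^(1 / 3), tolerance = 1e-12)
  # round trip: implied volume fraction equals the request
  expect_equal(35240 * (4 / 3) * pi * 0.5^3 / ((4 / 3) * pi * R^3), 0.15,
               tolerance = 1e-12)
  expect_equal(confinement_radius(8 * 0.15, 0.15), 1)
  expect_error(confinement_radius(100, 0.9), "0.64")
  expect_error(confinement_radius(-5, 0.15), "positive")
})

test_that("lamina shell is on-sphere, near-uniform and area-scaled", {
  lam <- build_lamina(10, spacing = 1)
  expect_equal(sqrt(rowSums(lam^2)), rep(10, nrow(lam)), tolerance = 1e-9)
  expect_lt(abs(nrow(lam) - 4 * pi * 100) / (4 * pi * 100), 0.1)
  d <- as.matrix(dist(lam))
  diag(d) <- Inf
  expect_gt(min(d), 0.5)
  # deterministic
  expect_identical(lam, build_lamina(10, spacing = 1))
})

test_that("pair energy is the truncated, shifted Lennard-Jones form", {
  eps <- 0.5
  shift <- 4 * eps * ((1 / 2.5)^12 - (1 / 2.5)^6)
  expect_equal(pair_energy(1, eps), 0 - shift)
  expect_gt(pair_energy(1, eps), 0)  # shift is negative at these cutoffs
  expect_equal(pair_energy(2^(1 / 6), eps), -eps - shift)
  expect_identical(pair_energy(2.6, eps), 0)
  expect_identical(pair_energy(2.5 + 1e-9, eps, cutoff = 2.5), 0)
  expect_error(pair_energy(0, eps), "positive")
})

test_that("bond registry obeys formation, rupture and single-bond rules", {
  beads <- tibble::tibble(bead_index = 1:3, chromosome = 1L,
                          compartment = "EU",
                          h3k27me3 = c(TRUE, TRUE, FALSE))
  lam <- rbind(c(0, 0, 10), c(1.0, 0, 10), c(5, 5, 10))
  cfg <- sim_config()
  # unbonded H3K27me3 bead within 1.5 sigma bonds to the nearest lamina bead
  st <- sim_state(rbind(c(0, 0, 8.6), c(5, 5, 0), c(0, 0, 9.9)),
                  beads, lam, radius = 10)
  st <- update_lamina_bonds(st, cfg)
  expect_identical(st$bonds, c(1L, 0L, 0L))

  # stretching past 2.5 sigma breaks the bond
  st$positions[1, ] <- c(0, 0, 7.4)
  st <- update_lamina_bonds(st, cfg)
  expect_identical(st$bonds[1], 0L)

  # an existing bond is kept even when another lamina bead comes closer
  st$positions[1, ] <- c(0, 0, 9.0)
  st <- update_lamina_bonds(st, cfg)
  expect_identical(st$bonds[1], 1L)
  st$positions[1, ] <- c(1.0, 0, 9.5)  # bead 2 of the lamina is now nearer
  st2 <- update_lamina_bonds(st, cfg)
  expect_identical(st2$bonds[1], 1L)   # still exactly one bond, unchanged
  # non-H3K27me3 beads never bond
  expect_identical(st2$bonds[3], 0L)
})

test_that("zero-temperature springs relax monotonically to rest length", {
  beads <- tibble::tibble(bead_index = 1:2, chromosome = 1L,
                          compartment = "EU", h3k27me3 = FALSE)
  cfg <- sim_config(temperature = 0, eps_EE = 0, eps_HH = 0, eps_cross = 0,
                    eps_wall = 0, lamina_bond_K = 0)
  st <- sim_state(rbind(c(0, 0, 0), c(3, 0, 0)), beads, radius = 100)
  dists <- numeric(20)
  for (i in 1:20) {
    st <- sim_step(st, cfg, n = 1, seed = i)
    dists[i] <- abs(st$positions[2, 1] - st$positions[1, 1])
  }
  expect_true(all(diff(dists) <= 1e-12))
  expect_lt(abs(dists[20] - 1), 0.05)
})

test_that("free diffusion satisfies the Einstein relation", {
  n <- 400
  st <- free_state(n)
  steps <- 1000
  st <- sim_step(st, free_config(), n = steps, seed = 11)
  msd <- mean(rowSums(st$positions^2))
  t <- steps * 0.01
  expect_lt(abs(msd - 6 * t) / (6 * t), 0.1)
})

test_that("non-interacting confined beads sample the sphere uniformly", {
  n <- 10000
  R <- 5
  st <- free_state(n, radius = R)
  st <- sim_step(st, free_config(), n = 4000, seed = 3)
  r <- sqrt(rowSums(st$positions^2))
  ks <- ks.test(r, function(q) pmin(1, pmax(0, (q / R)^3)))
  expect_gt(ks$p.value, 0.01)
  expect_lte(max(r), R + 1e-6)
})

test_that("very stiff lamina bonds persist once formed", {
  R <- 6
  lam <- build_lamina(R, 1)
  n <- 40
  beads <- tibble::tibble(bead_index = seq_len(n), chromosome = seq_len(n),
                          compartment = "EU", h3k27me3 = TRUE)
  # beads seeded 1 sigma inside lamina beads, so all bond immediately
  pos <- lam[seq_len(n), ] * (R - 1) / R
  cfg <- sim_config(lamina_bond_K = 1000, eps_EE = 0, eps_HH = 0,
                    eps_cross = 0, backbone_k = 0)
  st <- sim_state(pos, beads, lam, radius = R)
  st <- update_lamina_bonds(st, cfg)
  expect_true(all(st$bonds > 0))
  st <- sim_step(st, cfg, n = 10000, seed = 5)
  expect_gte(mean(st$bonds > 0), 0.99)
})

test_that("trajectories are reproducible, sized and confined", {
  spec <- genome_spec()
  beads <- partition_genome(spec, n_beads = 120)
  beads <- generate_h3k27me3_patches(beads, spec, seed = 2)
  cfg <- sim_config()
  t1 <- run_simulation(beads, cfg, steps = 300, stride = 50, seed = 9)
  t2 <- run_simulation(beads, cfg, steps = 300, stride = 50, seed = 9)
  expect_identical(length(t1$frames), 7L)  # floor(steps/stride) + 1
  expect_equal(t1$frames, t2$frames)
  expect_identical(t1$bonds, t2$bonds)

  t0 <- run_simulation(beads, cfg, steps = 0, stride = 1, seed = 9)
  expect_identical(length(t0$frames), 1L)

  td <- tidy(t1)
  expect_true(all(td$max_radius <= t1$radius + 1e-6))
  # bond registry only ever points from H3K27me3 beads
  for (b in t1$bonds) expect_true(all(b[!beads$h3k27me3] == 0))
  # lamina fixed over the run, bead count constant
  expect_identical(nrow(t1$frames[[1]]), nrow(beads))
  expect_error(run_simulation(beads, cfg, steps = 3, stride = 5), "stride")
})

test_that("xyz export tags bead classes and frames", {
  spec <- genome_spec()
  beads <- partition_genome(spec, n_beads = 40)
  beads <- generate_h3k27me3_patches(beads, spec, seed = 2)
  tr <- run_simulation(beads, sim_config(), steps = 10, stride = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(tr, f, frames = 1)
  lines <- readLines(f)
  n_total <- nrow(beads) + nrow(tr$lamina)
  expect_identical(as.integer(lines[1]), n_total)
  tags <- sub(" .*", "", lines[3:(2 + n_total)])
  expect_setequal(unique(tags), c("E", "P", "H", "L"))
})
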