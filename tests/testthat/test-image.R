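test_that("a noise-free sphere segments to its geometric volume", {
  vox <- c(0.25, 0.25, 0.25)
  arr <- sphere_stack(5, vox, dim = c(48, 48, 48), value = 100,
                      background = 2)
  m <- segment_nuclei(arr, vox, sigma = 1, min_volume = 20)
  expect_identical(m$n, 1L)
  vol_true <- 4 / 3 * pi * 125
  expect_lt(abs(m$summary$volume - vol_true) / vol_true, 0.05)
})

test_that("empty stacks and border-touching components are rejected", {
  vox <- c(0.25, 0.25, 0.25)
  expect_warning(m0 <- segment_nuclei(array(0, c(20, 20, 20)), vox),
                 "no nuclei")
  expect_identical(m0$n, 0L)
  # a sphere pushed into the stack border is discarded
  arr <- sphere_stack(3, vox, dim = c(30, 30, 30), centre_frac = c(0.02, 0.5, 0.5))
  expect_warning(mb <- segment_nuclei(arr, vox), "filters")
  expect_identical(mb$n, 0L)
})

test_that("two separated spheres segment independently", {
  vox <- c(0.25, 0.25, 0.25)
  dm <- c(40, 72, 40)
  a1 <- sphere_stack(3, vox, dim = dm, centre_frac = c(0.5, 0.25, 0.5))
  a2 <- sphere_stack(2.2, vox, dim = dm, centre_frac = c(0.5, 0.75, 0.5))
  arr <- pmax(a1, a2)
  m <- segment_nuclei(arr, vox)
  expect_identical(m$n, 2L)
  vols <- sort(m$summary$volume)
  expect_lt(abs(vols[1] - 4 / 3 * pi * 2.2^3) / (4 / 3 * pi * 2.2^3), 0.12)
  expect_lt(abs(vols[2] - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.12)
  # masks are disjoint by construction of the labelling
  expect_identical(sum(m$labels > 0), sum(m$summary$n_voxels))
})

test_that("nuclear statistics read only mask voxels", {
  vox <- c(0.25, 0.25, 0.25)
  dna <- sphere_stack(4, vox, dim = c(44, 44, 44), value = 80, background = 3)
  m <- segment_nuclei(dna, vox)
  mark <- array(7, dim(dna))               # uniform mark
  q <- quantify_nuclei(m, dna, mark)
  expect_equal(q$mean_mark_intensity, 7)
  expect_equal(q$total_dna_intensity, sum(dna[m$labels == 1]))

  # a bright cytoplasmic halo outside the mask cannot move the nuclear mean
  mark2 <- mark
  mark2[m$labels == 0] <- 500
  q2 <- quantify_nuclei(m, dna, mark2)
  expect_equal(q2$mean_mark_intensity, 7)

  # doubling voxel edges multiplies volume by 8 for the same mask
  m2 <- m
  m2$voxel_size <- vox * 2
  m2$summary$volume <- m2$summary$n_voxels * prod(vox * 2)
  q3 <- quantify_nuclei(m2, dna, mark)
  expect_equal(q3$volume, q$volume * 8)
})

test_that("puncta segmentation recovers counts and the volume filter", {
  r_for_vol <- function(v) (3 * v / (4 * pi))^(1 / 3)
  st <- puncta_stack(rep(r_for_vol(0.05), 5))
  m <- segment_nuclei(st$dna, st$vox)
  p <- segment_puncta(m, st$mark)
  expect_identical(nrow(p), 5L)
  expect_true(all(abs(p$volume - 0.05) / 0.05 < 0.2))
  # no voxel belongs to two puncta and all survive the volume filter
  expect_true(all(p$volume >= 0.01))

  # a 0.005 um^3 blob is filtered out
  st2 <- puncta_stack(c(r_for_vol(0.05), r_for_vol(0.005)))
  m2 <- segment_nuclei(st2$dna, st2$vox)
  p2 <- segment_puncta(m2, st2$mark)
  expect_identical(nrow(p2), 1L)

  # flat nuclei yield no puncta
  st3 <- puncta_stack(numeric(0))
  m3 <- segment_nuclei(st3$dna, st3$vox)
  expect_identical(nrow(segment_puncta(m3, st3$mark)), 0L)
})

test_that("radial profiles are flat for uniform intensity and scale-free", {
  vox <- c(0.2, 0.2, 0.2)
  dna <- sphere_stack(3, vox, dim = c(40, 40, 40), value = 100,
                      background = 4)
  m <- segment_nuclei(dna, vox)
  uni <- array(11, dim(dna))
  prof <- radial_distribution(m, uni, n_shells = 5)
  expect_equal(prof$ratio, rep(1, 5), tolerance = 1e-9)

  # ratio is invariant to global intensity scaling
  prof2 <- radial_distribution(m, uni * 37, n_shells = 5)
  expect_equal(prof2$ratio, prof$ratio)

  # a peripheral rim raises shell 1 over the core
  rim <- array(10, dim(dna))
  depth <- array(chromatether:::cpp_edt3(m$labels == 1, dim(dna), vox),
                 dim(dna))
  rim[m$labels == 1] <- 10
  rim[m$labels == 1 & depth < 0.6] <- 30
  prof3 <- radial_distribution(m, rim, n_shells = 5)
  expect_gt(prof3$ratio[1], prof3$ratio[4])
  expect_error(radial_distribution(m, uni, nucleus = 2), "empty nucleus")
})
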