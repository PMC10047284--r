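# shared fixtures and independent oracles

# brute-force O(n^2) union-find over the contact graph; reference for the
# cell-list component decomposition
oracle_components <- function(pos, cutoff) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) a <- parent[a]
    a
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= cutoff) {
        ra <- find(i); rb <- find(j)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# same partition up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(tapply(b, a, function(x) length(unique(x))) == 1) &&
    all(tapply(a, b, function(x) length(unique(x))) == 1)
}

# tiny free-bead state (no chains, no lamina) for integrator checks
free_state <- function(n, radius = 1e6) {
  sim_state(matrix(0, n, 3), radius = radius)
}

free_config <- function(...) {
  sim_config(eps_EE = 0, eps_HH = 0, eps_cross = 0, eps_wall = 0,
             backbone_k = 0, lamina_bond_K = 0, ...)
}

# hierarchical per-nucleus measures without any imaging, for mixed-model
# checks
make_quants <- function(effect_pct, n_larvae = 5, n_nuclei = 10,
                        larva_sd = 0.05, nucleus_sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (g in c("control", "mutant")) {
      fac <- if (g == "mutant") 1 + effect_pct / 100 else 1
      for (l in seq_len(n_larvae)) {
        lf <- rlnorm(1, 0, larva_sd)
        v <- 100 * fac * lf * rlnorm(n_nuclei, 0, nucleus_sd)
        rows[[length(rows) + 1]] <- tibble::tibble(
          genotype = g, larva_id = paste0(g, l), muscle_id = "M1",
          mean_mark_intensity = v, volume = 500)
      }
    }
    dplyr::bind_rows(rows)
  })
}

# ellipsoid stack builder for segmentation fixtures
sphere_stack <- function(radius_um, voxel = c(0.25, 0.25, 0.25),
                         dim = NULL, value = 100, background = 5,
                         centre_frac = c(0.5, 0.5, 0.5)) {
  dm <- dim %||% rep(ceiling(2 * radius_um / voxel[1]) + 9, 3)
  centre <- dm * centre_frac
  a1 <- (seq_len(dm[1]) - centre[1]) * voxel[1]
  a2 <- (seq_len(dm[2]) - centre[2]) * voxel[2]
  a3 <- (seq_len(dm[3]) - centre[3]) * voxel[3]
  q <- outer(outer(a1^2, a2^2, `+`), a3^2, `+`)
  arr <- array(background, dm)
  arr[q <= radius_um^2] <- value
  arr
}

`%||%` <- rlang::`%||%`

puncta_stack <- function(radii_um, vox = c(0.1, 0.1, 0.1), nucleus_r = 2.2,
                         value = 100, contrast = 4) {
  dm <- rep(ceiling(2 * (nucleus_r + 0.8) / vox[1]), 3)
  dna <- sphere_stack(nucleus_r, vox, dim = dm, value = value, background = 4)
  mark <- array(20, dm)
  mark[dna > 50] <- 50
  centre <- dm / 2
  # place puncta along a diagonal, well separated
  offs <- seq(-1.2, 1.2, length.out = max(2, length(radii_um)))
  for (i in seq_along(radii_um)) {
    cen <- centre + offs[i] / vox
    ii <- seq_len(dm[1]); jj <- seq_len(dm[2]); kk <- seq_len(dm[3])
    d2 <- outer(outer(((ii - cen[1]) * vox[1])^2, ((jj - cen[2]) * vox[2])^2,
                      `+`), ((kk - cen[3]) * vox[3])^2, `+`)
    mark[d2 <= radii_um[i]^2] <- 50 * contrast
  }
  list(dna = dna, mark = mark, vox = vox)
}
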