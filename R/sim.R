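#' Simulation configuration
#'
#' Parameters of the confined bead-spring chromatin model. Energies are in
#' units of kBT, lengths in bead diameters (sigma), time in the Brownian
#' unit tau; integration is overdamped Langevin with timestep `timestep` and
#' friction `damping`.
#'
#' Euchromatin-euchromatin contacts attract with `eps_EE`, heterochromatin
#' (PCH and H3K27me3 alike) with `eps_HH`, and mixed contacts with
#' `eps_cross`; all through a Lennard-Jones potential truncated and
#' energy-shifted to zero at `lj_cutoff`. H3K27me3 beads may each hold at
#' most one harmonic bond (spring constant `lamina_bond_K`, rest length
#' `bond_rest`) to a fixed lamina bead; bonds form when an unbonded
#' H3K27me3 bead comes within `bond_form_dist` of a lamina bead and break
#' when stretched beyond `bond_break_dist`.
#'
#' @param eps_EE,eps_HH,eps_cross LJ attraction strengths, kBT.
#' @param lj_cutoff LJ truncation distance, sigma.
#' @param backbone_k,backbone_rest Backbone spring constant (kBT/sigma^2) and
#'   rest length (sigma).
#' @param lamina_bond_K Lamina bond spring constant, kBT/sigma^2 (the
#'   strong/weak tethering regimes of interest are 10 and 1.5).
#' @param bond_form_dist,bond_break_dist,bond_rest Bond formation, rupture
#'   and rest distances, sigma.
#' @param volume_fraction Chromatin volume fraction inside the confining
#'   sphere; sets the confinement radius via [confinement_radius()].
#' @param timestep,damping,temperature Integrator timestep (tau), friction
#'   gamma (1/tau) and kBT.
#' @param eps_wall Strength of the purely repulsive (WCA) wall and
#'   lamina-bead steric interactions, kBT; 0 leaves only the reflecting
#'   boundary.
#' @param force_cap Cap on the net force magnitude per bead (prevents
#'   blow-up from deep core overlaps during equilibration).
#' @param registry_stride Steps between bond-registry updates.
#' @param lamina_spacing Target lamina bead spacing on the shell, sigma.
#' @param n_relax Zero-temperature relaxation steps applied to the initial
#'   random-walk configuration before sampling starts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(eps_EE = 0.35, eps_HH = 0.5, eps_cross = 0.3,
                       lj_cutoff = 2.5,
                       backbone_k = 100, backbone_rest = 1,
                       lamina_bond_K = 10, bond_form_dist = 1.5,
                       bond_break_dist = 2.5, bond_rest = 1,
                       volume_fraction = 0.15,
                       timestep = 0.01, damping = 1, temperature = 1,
                       eps_wall = 1, force_cap = 50,
                       registry_stride = 10, lamina_spacing = 1,
                       n_relax = 500) {
  if (bond_form_dist >= bond_break_dist)
    abort("bond_form_dist must be smaller than bond_break_dist")
  if (volume_fraction <= 0 || volume_fraction >= 0.64)
    abort("volume_fraction must lie in (0, 0.64)")
  if (any(c(eps_EE, eps_HH, eps_cross, eps_wall) < 0))
    abort("LJ strengths must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

#' Confinement radius for a target volume fraction
#'
#' Radius R (sigma) of the sphere in which `n_beads` beads of diameter 1
#' occupy the given volume fraction: `R = (n_beads / (8 * volume_fraction))^(1/3)`.
#'
#' @param n_beads Bead count.
#' @param volume_fraction Target volume fraction in (0, 0.64).
#' @return Radius in sigma.
#' @examples
#' confinement_radius(35240, 0.15)
#' @export
confinement_radius <- function(n_beads, volume_fraction) {
  if (n_beads <= 0) abort("n_beads must be positive")
  if (volume_fraction <= 0 || volume_fraction >= 0.64)
    abort("volume_fraction must lie in (0, 0.64)")
  (n_beads / (8 * volume_fraction))^(1 / 3)
}

#' Near-uniform lamina bead shell
#'
#' Places points on the sphere of radius `R` with a Fibonacci lattice, at a
#' count chosen so the nearest-neighbour spacing is approximately `spacing`.
#' Deterministic.
#'
#' @param R Sphere radius, sigma.
#' @param spacing Target nearest-neighbour spacing, sigma.
#' @return An n x 3 matrix of coordinates.
#' @export
build_lamina <- function(R, spacing = 1) {
  if (R <= 1) abort("R must exceed one bead diameter")
  # one bead per spacing^2 of shell area
  n <- max(12L, round(4 * pi * R^2 / spacing^2))
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i / phi
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = R * r * cos(theta), y = R * r * sin(theta), z = R * z)
}

#' Truncated, energy-shifted Lennard-Jones pair energy
#'
#' `4 eps [(1/r)^12 - (1/r)^6]` shifted so the energy is zero at the cutoff,
#' and identically zero beyond it.
#'
#' @param r Pair distance, sigma (> 0).
#' @param eps Well depth, kBT.
#' @param cutoff Truncation distance, sigma.
#' @return Energy in kBT.
#' @export
pair_energy <- function(r, eps, cutoff = 2.5) {
  if (any(r <= 0)) abort("r must be positive")
  vapply(r, cpp_pair_energy, numeric(1), eps = eps, cutoff = cutoff)
}

sim_par_list <- function(config, R) {
  list(eps_EE = config$eps_EE, eps_HH = config$eps_HH,
       eps_cross = config$eps_cross, lj_cutoff = config$lj_cutoff,
       backbone_k = config$backbone_k, backbone_rest = config$backbone_rest,
       lamina_bond_K = config$lamina_bond_K,
       bond_form_dist = config$bond_form_dist,
       bond_break_dist = config$bond_break_dist, bond_rest = config$bond_rest,
       radius = R, timestep = config$timestep, damping = config$damping,
       temperature = config$temperature, eps_wall = config$eps_wall,
       force_cap = config$force_cap,
       registry_stride = as.integer(config$registry_stride))
}

bead_type_codes <- function(beads) {
  ifelse(beads$h3k27me3, 2L, ifelse(beads$compartment == "PCH", 1L, 0L))
}

#' Construct a simulation state
#'
#' Bundles bead positions, the fixed lamina shell, the bond registry and the
#' bead metadata needed to advance the dynamics.
#'
#' @param positions n x 3 matrix of bead coordinates (sigma).
#' @param beads Bead tibble ([partition_genome()] output) or `NULL` for
#'   unlabelled free beads.
#' @param lamina m x 3 matrix of lamina coordinates (may have zero rows).
#' @param radius Confinement radius, sigma.
#' @param bonds Integer vector: 0 = unbonded, else 1-based lamina index.
#' @param step_count Steps already taken.
#' @return A list of class `sim_state`.
#' @export
sim_state <- function(positions, beads = NULL, lamina = NULL, radius,
                      bonds = NULL, step_count = 0L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(beads)) {
    beads <- tibble::tibble(bead_index = seq_len(n),
                            chromosome = rep(1L, n),
                            compartment = rep("EU", n),
                            h3k27me3 = rep(FALSE, n))
  }
  lamina <- if (is.null(lamina)) matrix(numeric(0), 0, 3) else as.matrix(lamina)
  bonds <- bonds %||% integer(n)
  stopifnot(nrow(beads) == n, length(bonds) == n)
  structure(list(positions = positions, beads = beads, lamina = lamina,
                 radius = radius, bonds = as.integer(bonds),
                 step_count = as.integer(step_count)),
            class = "sim_state")
}

#' Refresh the lamina bond registry
#'
#' Removes bonds stretched beyond `bond_break_dist`, then bonds every
#' unbonded H3K27me3 bead that has a lamina bead within `bond_form_dist` to
#' the nearest such bead. Only H3K27me3 beads ever hold bonds, and at most
#' one each; a lamina bead may host several bonds.
#'
#' @param state A [sim_state()].
#' @param config A [sim_config()].
#' @return The state with an updated bond registry.
#' @export
update_lamina_bonds <- function(state, config) {
  stopifnot(inherits(state, "sim_state"))
  is_h3k <- bead_type_codes(state$beads) == 2L
  state$bonds <- cpp_update_bonds(state$positions, is_h3k, state$lamina,
                                  state$bonds, config$bond_form_dist,
                                  config$bond_break_dist)
  state
}

#' Advance the dynamics
#'
#' Runs `n` overdamped Langevin steps: forces are backbone springs, pairwise
#' truncated LJ with type-dependent strength, active lamina-bond springs,
#' lamina-bead sterics and the repulsive wall; positions move by
#' `F/gamma * dt` plus Gaussian noise of variance `2 kBT dt / gamma` per
#' coordinate, then reflect off the confining sphere. The bond registry is
#' refreshed every `registry_stride` steps.
#'
#' @param state A [sim_state()].
#' @param config A [sim_config()].
#' @param n Number of steps.
#' @param seed Integer seed for the noise stream.
#' @return The advanced state.
#' @export
sim_step <- function(state, config, n = 1, seed = 1) {
  stopifnot(inherits(state, "sim_state"))
  out <- cpp_run_langevin(state$positions, bead_type_codes(state$beads),
                          as.integer(state$beads$chromosome), state$lamina,
                          state$bonds, sim_par_list(config, state$radius),
                          as.integer(n), 1L, as.double(seed),
                          sample_frames = FALSE)
  state$positions <- out$final_positions
  state$bonds <- out$final_bonds
  state$step_count <- state$step_count + as.integer(n)
  state
}

init_positions <- function(beads, R) {
  n <- nrow(beads)
  pos <- matrix(0, n, 3)
  for (ch in unique(beads$chromosome)) {
    idx <- which(beads$chromosome == ch)
    p <- matrix(0, length(idx), 3)
    repeat {
      start <- rnorm(3)
      start <- start / sqrt(sum(start^2)) * runif(1)^(1 / 3) * 0.7 * R
      if (sqrt(sum(start^2)) < 0.8 * R) break
    }
    p[1, ] <- start
    for (i in seq_along(idx)[-1]) {
      step <- rnorm(3)
      cand <- p[i - 1, ] + step / sqrt(sum(step^2))
      r <- sqrt(sum(cand^2))
      if (r > 0.95 * R) cand <- cand * (0.95 * R) / r  # fold back inside
      p[i, ] <- cand
    }
    pos[idx, ] <- p
  }
  pos
}

#' Run a chromatin simulation
#'
#' Builds the confinement sphere and lamina shell for the bead count and
#' configured volume fraction, seeds each chromosome as a confined random
#' walk, relaxes overlaps with a short zero-temperature capped-force descent,
#' then integrates `steps` Langevin steps, sampling every `stride` steps.
#' The sampled trajectory always includes the relaxed initial state as
#' frame 0, so it holds `floor(steps/stride) + 1` frames. Fully reproducible
#' given `seed`.
#'
#' @param beads Bead tibble ([partition_genome()], typically after
#'   [generate_h3k27me3_patches()]).
#' @param config A [sim_config()].
#' @param steps Langevin steps to integrate (>= stride or 0).
#' @param stride Sampling stride (>= 1).
#' @param seed Integer seed.
#' @return A `chromatin_trajectory`: list with `frames` (list of n x 3
#'   matrices), `bonds` (list of integer registries), `beads`, `lamina`,
#'   `radius`, `config`, `stride`, `steps`, `seed`.
#' @export
run_simulation <- function(beads, config = sim_config(), steps, stride = 1,
                           seed = 1) {
  stopifnot(stride >= 1)
  if (steps > 0 && steps < stride) abort("steps must be >= stride (or 0)")
  n <- nrow(beads)
  R <- confinement_radius(n, config$volume_fraction)
  lamina <- build_lamina(R, config$lamina_spacing)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    pos <- init_positions(beads, R)
    noise_seed <- sample.int(.Machine$integer.max, 2)
  })
  types <- bead_type_codes(beads)
  chain <- as.integer(beads$chromosome)
  par <- sim_par_list(config, R)

  if (config$n_relax > 0) {
    relax_par <- par
    relax_par$temperature <- 0
    relax_par$force_cap <- 10
    relax_par$lamina_bond_K <- 0  # no tethering during overlap removal
    out <- cpp_run_langevin(pos, types, chain, lamina, integer(n), relax_par,
                            as.integer(config$n_relax), 1L,
                            as.double(noise_seed[1]), sample_frames = FALSE)
    pos <- out$final_positions
  }

  out <- cpp_run_langevin(pos, types, chain, lamina, integer(n), par,
                          as.integer(steps), as.integer(stride),
                          as.double(noise_seed[2]), sample_frames = TRUE)
  structure(list(frames = out$frames, bonds = out$bonds, beads = beads,
                 lamina = lamina, radius = R, config = config,
                 stride = as.integer(stride), steps = as.integer(steps),
                 seed = seed),
            class = "chromatin_trajectory")
}

#' Extract one frame of a trajectory as a simulation state
#'
#' @param traj A `chromatin_trajectory`.
#' @param frame Frame number (1-based; frame 1 is the initial state).
#' @return A [sim_state()].
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "chromatin_trajectory"))
  if (frame < 1 || frame > length(traj$frames)) abort("frame out of range")
  sim_state(traj$frames[[frame]], traj$beads, traj$lamina, traj$radius,
            traj$bonds[[frame]],
            step_count = (frame - 1L) * traj$stride)
}

#' @export
print.chromatin_trajectory <- function(x, ...) {
  cat("<chromatin_trajectory> ", nrow(x$beads), " beads, ",
      length(x$frames), " frames (stride ", x$stride, "), R = ",
      round(x$radius, 2), " sigma, K = ", x$config$lamina_bond_K, "\n",
      sep = "")
  invisible(x)
}

#' Per-frame summary of a trajectory
#'
#' @param x A `chromatin_trajectory`.
#' @param ... Unused.
#' @return Tibble with one row per frame: `frame`, `step`, `n_bonded`
#'   (H3K27me3 beads currently lamina-bonded), `frac_bonded` (of all
#'   H3K27me3 beads), `max_radius`.
#' @export
tidy.chromatin_trajectory <- function(x, ...) {
  n_h3k <- sum(x$beads$h3k27me3)
  tibble::tibble(
    frame = seq_along(x$frames),
    step = (seq_along(x$frames) - 1L) * x$stride,
    n_bonded = vapply(x$bonds, function(b) sum(b > 0), integer(1)),
    frac_bonded = if (n_h3k > 0) .data$n_bonded / n_h3k else 0,
    max_radius = vapply(x$frames, function(p) sqrt(max(rowSums(p^2))),
                        numeric(1)))
}

#' Export a trajectory frame in XYZ format
#'
#' Element tags: E (euchromatin), P (PCH), H (H3K27me3), L (lamina).
#'
#' @param traj A `chromatin_trajectory`.
#' @param path Output file.
#' @param frames Frames to write (default all).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, frames = seq_along(traj$frames)) {
  tags <- c("E", "P", "H")[bead_type_codes(traj$beads) + 1L]
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    p <- rbind(traj$frames[[f]], traj$lamina)
    tg <- c(tags, rep("L", nrow(traj$lamina)))
    writeLines(c(as.character(nrow(p)), paste("frame", f)), con)
    writeLines(sprintf("%s %.5f %.5f %.5f", tg, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}
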