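#' Synthetic nucleus cohort specification
#'
#' Describes a two-genotype cohort of 3D two-channel nucleus stacks with a
#' larva / muscle / nucleus sampling hierarchy. Mark intensity is
#' multiplicative: grand mean x genotype factor x log-normal larva, muscle
#' and nucleus factors (so group effects are percent changes and
#' intensities stay positive). Each stack holds one ellipsoidal nucleus
#' (DNA channel: bright interior over a dim cytoplasmic background, with an
#' optional peripheral rim), a mark channel at the nucleus' latent mean with
#' optional bright spherical puncta, plus Gaussian read noise and optional
#' Poisson shot noise.
#'
#' @param n_larvae Larvae per genotype.
#' @param n_muscles Muscles per larva.
#' @param n_nuclei Nuclei per muscle.
#' @param genotypes Genotype labels (first = control).
#' @param radius_um Nuclear radius range (uniform draw), um.
#' @param voxel_size Voxel edges, um, in array-dimension order.
#' @param margin_um Cytoplasmic margin around the nucleus, um.
#' @param genotype_effect Percent change of the mutant mark mean
#'   (e.g. 43 for +43%, -37 for a reduction).
#' @param volume_effect Percent change of mutant nuclear radius^3 (0 keeps
#'   volumes matched).
#' @param larva_sd,muscle_sd,nucleus_sd Log-normal sdlog of the random
#'   factors.
#' @param grand_mean Control-group mark mean, a.u.
#' @param dna_level DNA-channel interior intensity, a.u.
#' @param cyto_frac Cytoplasmic background as a fraction of the channel
#'   level.
#' @param peripheral_bias Strength of the DNA peripheral rim (0 = flat;
#'   0.5 raises the outer 20% depth shell by 50%).
#' @param puncta List: `n_mean` (Poisson mean count), `vol_mean_um3` and
#'   `vol_sdlog` (log-normal punctum volume), `contrast` (punctum intensity
#'   as a multiple of the nuclear mark level), `volume_effect` (percent
#'   change of mutant punctum volume). `n_mean = 0` disables puncta.
#' @param noise_sd Gaussian read noise sd as a fraction of `grand_mean`.
#' @param poisson_noise Apply Poisson shot noise?
#' @return A list of class `synth_nuclei_spec`.
#' @export
synth_nuclei_spec <- function(n_larvae = 5, n_muscles = 3, n_nuclei = 10,
                              genotypes = c("control", "mutant"),
                              radius_um = c(2.2, 2.9),
                              voxel_size = c(0.5, 0.3, 0.3),
                              margin_um = 1.0,
                              genotype_effect = 0, volume_effect = 0,
                              larva_sd = 0.05, muscle_sd = 0.05,
                              nucleus_sd = 0.12,
                              grand_mean = 100, dna_level = 100,
                              cyto_frac = 0.15, peripheral_bias = 0,
                              puncta = list(n_mean = 0, vol_mean_um3 = 0.12,
                                            vol_sdlog = 0.3, contrast = 3,
                                            volume_effect = 0),
                              noise_sd = 0.05, poisson_noise = FALSE) {
  if (any(c(larva_sd, muscle_sd, nucleus_sd) < 0))
    abort("variance components must be >= 0")
  if (any(radius_um <= 0)) abort("radii must be positive")
  structure(as.list(environment()), class = "synth_nuclei_spec")
}

#' Generate a synthetic nucleus cohort
#'
#' @param spec A [synth_nuclei_spec()].
#' @param seed Integer seed; the cohort is a pure function of
#'   `(spec, seed)`.
#' @param dir Optional directory: writes per-stack two-channel TIFFs (via
#'   the tiff package), a `samples.csv` and a `truth.tsv`.
#' @return A list of class `synth_nuclei`: `samples` (tibble: `stack`,
#'   `genotype`, `larva_id`, `muscle_id`, `nucleus_id`), `stacks` (list of
#'   `list(dna, mark, voxel_size)`), and `truth` (per-nucleus latent
#'   factors, true mark mean, true radius/volume and true puncta summary).
#' @export
gen_nuclei_cohort <- function(spec, seed, dir = NULL) {
  stopifnot(inherits(spec, "synth_nuclei_spec"))
  geno_factor <- c(1, 1 + spec$genotype_effect / 100)
  vol_factor <- c(1, 1 + spec$volume_effect / 100)
  punc_vol_factor <- c(1, 1 + (spec$puncta$volume_effect %||% 0) / 100)

  grid <- tidyr::expand_grid(genotype = spec$genotypes,
                             larva = seq_len(spec$n_larvae),
                             muscle = seq_len(spec$n_muscles),
                             nucleus = seq_len(spec$n_nuclei))
  stacks <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  withr::with_seed(as.integer(seed), {
    lf <- array(rlnorm(2 * spec$n_larvae, 0, spec$larva_sd),
                c(2, spec$n_larvae))
    mf <- array(rlnorm(2 * spec$n_larvae * spec$n_muscles, 0,
                       spec$muscle_sd),
                c(2, spec$n_larvae, spec$n_muscles))
    for (i in seq_len(nrow(grid))) {
      g <- match(grid$genotype[i], spec$genotypes)
      la <- grid$larva[i]; mu <- grid$muscle[i]
      nf <- rlnorm(1, 0, spec$nucleus_sd)
      mark_mean <- spec$grand_mean * geno_factor[g] * lf[g, la] *
        mf[g, la, mu] * nf
      radius <- runif(1, spec$radius_um[1], spec$radius_um[2]) *
        vol_factor[g]^(1 / 3)
      res <- render_nucleus(spec, radius, mark_mean,
                            punc_vol_factor[g])
      stacks[[i]] <- res$stack
      truth[[i]] <- tibble::tibble(
        stack = i, genotype = grid$genotype[i],
        larva_id = paste0(grid$genotype[i], "_L", la),
        muscle_id = paste0("M", mu), nucleus_id = grid$nucleus[i],
        latent_mark_mean = mark_mean, latent_radius = radius,
        latent_volume = 4 / 3 * pi * radius^3,
        larva_factor = lf[g, la], muscle_factor = mf[g, la, mu],
        nucleus_factor = nf,
        n_puncta = res$n_puncta, mean_punctum_volume = res$mean_punc_vol)
    }
  })
  samples <- tibble::tibble(stack = seq_len(nrow(grid)),
                            genotype = grid$genotype,
                            larva_id = paste0(grid$genotype, "_L",
                                              grid$larva),
                            muscle_id = paste0("M", grid$muscle),
                            nucleus_id = grid$nucleus)
  out <- structure(list(samples = samples, stacks = stacks,
                        truth = bind_rows(truth), spec = spec, seed = seed),
                   class = "synth_nuclei")
  if (!is.null(dir)) write_nuclei_cohort(out, dir)
  out
}

render_nucleus <- function(spec, radius, mark_mean, punc_vol_factor) {
  vs <- spec$voxel_size
  dm <- as.integer(ceiling((2 * radius + 2 * spec$margin_um) / vs))
  # centre jitter keeps segmentation honest about sub-voxel placement
  centre <- (dm + 1) / 2 + runif(3, -0.5, 0.5)
  ax <- lapply(1:3, function(a) ((seq_len(dm[a]) - centre[a]) * vs[a]))
  # squared normalised ellipsoid radius via broadcasting
  e1 <- (ax[[1]] / radius)^2
  e2 <- (ax[[2]] / radius)^2
  e3 <- (ax[[3]] / radius)^2
  q <- outer(outer(e1, e2, `+`), e3, `+`)
  inside <- q <= 1

  dna <- array(spec$dna_level * spec$cyto_frac, dm)
  dna[inside] <- spec$dna_level
  if (spec$peripheral_bias != 0) {
    # raise the outer 20% (by normalised radius) of the nucleus
    rim <- inside & q > 0.8^2
    dna[rim] <- dna[rim] * (1 + spec$peripheral_bias)
  }
  mark <- array(mark_mean * spec$cyto_frac, dm)
  mark[inside] <- mark_mean

  n_puncta <- 0L
  mean_pv <- NA_real_
  if ((spec$puncta$n_mean %||% 0) > 0) {
    n_puncta <- rpois(1, spec$puncta$n_mean)
    if (n_puncta > 0) {
      pv <- rlnorm(n_puncta,
                   log(spec$puncta$vol_mean_um3 * punc_vol_factor) -
                     spec$puncta$vol_sdlog^2 / 2,
                   spec$puncta$vol_sdlog)
      pr <- (3 * pv / (4 * pi))^(1 / 3)
      mean_pv <- mean(pv)
      centres <- matrix(numeric(0), 0, 3)
      radii <- numeric(0)
      for (j in seq_len(n_puncta)) {
        # punctum centre well inside the nucleus; puncta are distinct
        # objects, so candidates overlapping a placed punctum are redrawn
        for (try in 1:200) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          rad <- radius * runif(1)^(1 / 3) * 0.85
          cen_um <- u * rad
          if (sqrt(sum(cen_um^2)) + pr[j] >= 0.97 * radius) next
          if (nrow(centres) > 0) {
            dd <- sqrt(rowSums(sweep(centres, 2, cen_um)^2))
            if (any(dd < radii + pr[j] + 0.12)) next
          }
          break
        }
        centres <- rbind(centres, cen_um)
        radii <- c(radii, pr[j])
        cen_vox <- cen_um / vs + centre
        lo <- pmax(1L, floor(cen_vox - pr[j] / vs - 1))
        hi <- pmin(dm, ceiling(cen_vox + pr[j] / vs + 1))
        ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
        d2 <- outer(outer(((ii - cen_vox[1]) * vs[1])^2,
                          ((jj - cen_vox[2]) * vs[2])^2, `+`),
                    ((kk - cen_vox[3]) * vs[3])^2, `+`)
        sub <- mark[ii, jj, kk]
        sub[d2 <= pr[j]^2] <- mark_mean * (1 + spec$puncta$contrast)
        mark[ii, jj, kk] <- sub
      }
    }
  }

  if (spec$poisson_noise) {
    dna <- array(rpois(length(dna), pmax(dna, 0)), dm)
    mark <- array(rpois(length(mark), pmax(mark, 0)), dm)
  }
  if (spec$noise_sd > 0) {
    dna <- dna + rnorm(length(dna), 0, spec$noise_sd * spec$dna_level)
    mark <- mark + rnorm(length(mark), 0, spec$noise_sd * spec$grand_mean)
  }
  list(stack = list(dna = dna, mark = mark, voxel_size = vs),
       n_puncta = n_puncta, mean_punc_vol = mean_pv)
}

#' Write a synthetic cohort to disk
#'
#' One two-page-per-slice TIFF per stack (channel-interleaved z-planes,
#' 32-bit float), a `samples.csv` mapping files to genotype / larva /
#' muscle ids and voxel sizes, and the ground-truth table.
#'
#' @param cohort A `synth_nuclei` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_nuclei_cohort <- function(cohort, dir) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("the tiff package is required to write stacks")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort$spec
  # one cohort-wide intensity scale so per-stack means stay comparable
  scale <- 20 * max(spec$dna_level,
                    spec$grand_mean * (1 + (spec$puncta$contrast %||% 0)))
  files <- character(length(cohort$stacks))
  for (i in seq_along(cohort$stacks)) {
    st <- cohort$stacks[[i]]
    dm <- dim(st$dna)
    planes <- list()
    for (k in seq_len(dm[1])) {  # first array dim = z
      planes[[2 * k - 1]] <- pmin(pmax(st$dna[k, , ] / scale, 0), 1)
      planes[[2 * k]] <- pmin(pmax(st$mark[k, , ] / scale, 0), 1)
    }
    files[i] <- file.path(dir, sprintf("stack_%04d.tif", i))
    tiff::writeTIFF(planes, files[i], bits.per.sample = 32L)
  }
  samples <- cohort$samples
  samples$file <- basename(files)
  samples$intensity_scale <- scale
  samples$voxel_z <- cohort$spec$voxel_size[1]
  samples$voxel_y <- cohort$spec$voxel_size[2]
  samples$voxel_x <- cohort$spec$voxel_size[3]
  utils::write.csv(samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
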