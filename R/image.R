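#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance over a fixed-width histogram.
#'
#' @param x Numeric vector (or array) of intensities.
#' @param n_bins Histogram bins.
#' @return Threshold value; voxels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                           n_bins))
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]; tot_mu <- mu[n_bins]
  w0 <- w[-n_bins]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  m0 <- mu[-n_bins] / w0
  m1 <- (tot_mu - mu[-n_bins]) / w1
  bc <- w0 * w1 * (m0 - m1)^2
  bc[!valid] <- -Inf
  edges[which.max(bc) + 1]
}

#' Segment nuclei from a DNA-channel stack
#'
#' Gaussian denoising (sigma in voxels), a global Otsu threshold, 3D
#' 26-connected components, then removal of components touching the stack
#' boundary or smaller than `min_volume`.
#'
#' @param dna 3D array, DNA (e.g. Hoechst) channel.
#' @param voxel_size Numeric length-3, voxel edge lengths in micrometres, in
#'   array-dimension order.
#' @param sigma Denoising sigma, voxels (scalar or length 3).
#' @param min_volume Minimum nucleus volume, um^3.
#' @param exclude_border Drop components touching the array border?
#' @return A list of class `nucleus_masks`: `labels` (integer array, 0 =
#'   background), `n`, `voxel_size`, and `summary` (tibble: `nucleus`,
#'   `n_voxels`, `volume`).
#' @export
segment_nuclei <- function(dna, voxel_size, sigma = 1, min_volume = 20,
                           exclude_border = TRUE) {
  stopifnot(length(dim(dna)) == 3)
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  sigma <- rep_len(as.numeric(sigma), 3)
  dm <- dim(dna)
  sm <- array(cpp_gauss_blur3(as.numeric(dna), dm, sigma), dm)
  thr <- otsu_threshold(sm)
  mask <- sm > thr
  lab <- array(cpp_label3(mask, dm), dm)
  vvol <- prod(voxel_size)
  if (max(lab) == 0) {
    warn("no nuclei found")
    return(new_nucleus_masks(array(0L, dm), voxel_size))
  }
  keep <- seq_len(max(lab))
  if (exclude_border) {
    border <- unique(c(lab[c(1, dm[1]), , ], lab[, c(1, dm[2]), ],
                       lab[, , c(1, dm[3])]))
    keep <- setdiff(keep, border)
  }
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- keep[sizes[keep] * vvol >= min_volume]
  if (length(keep) == 0) {
    warn("no nuclei survive the border/volume filters")
    return(new_nucleus_masks(array(0L, dm), voxel_size))
  }
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- array(0L, dm)
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  new_nucleus_masks(out, voxel_size)
}

new_nucleus_masks <- function(labels, voxel_size) {
  n <- max(labels)
  sizes <- if (n > 0) tabulate(labels, nbins = n) else integer()
  structure(list(labels = labels, n = n, voxel_size = voxel_size,
                 summary = tibble::tibble(
                   nucleus = seq_len(n), n_voxels = sizes,
                   volume = sizes * prod(voxel_size))),
            class = "nucleus_masks")
}

#' @export
print.nucleus_masks <- function(x, ...) {
  cat("<nucleus_masks>", x$n, "nuclei in a",
      paste(dim(x$labels), collapse = "x"), "stack\n")
  invisible(x)
}

#' Per-nucleus intensity and volume measures
#'
#' Statistics are computed strictly over mask voxels, so cytoplasmic
#' background never enters the nuclear means.
#'
#' @param masks A `nucleus_masks` from [segment_nuclei()].
#' @param dna DNA-channel array (same shape as the mask).
#' @param mark Mark-channel array, or `NULL`.
#' @return Tibble with one row per nucleus: `nucleus`, `volume` (um^3),
#'   `mean_mark_intensity`, `total_dna_intensity`.
#' @export
quantify_nuclei <- function(masks, dna, mark = NULL) {
  stopifnot(inherits(masks, "nucleus_masks"))
  lab <- masks$labels
  n <- masks$n
  if (n == 0)
    return(tibble::tibble(nucleus = integer(), volume = numeric(),
                          mean_mark_intensity = numeric(),
                          total_dna_intensity = numeric()))
  idx <- lab > 0
  f <- factor(lab[idx], levels = seq_len(n))
  nv <- tabulate(f, nbins = n)
  tibble::tibble(
    nucleus = seq_len(n),
    volume = nv * prod(masks$voxel_size),
    mean_mark_intensity = if (is.null(mark)) NA_real_ else
      as.numeric(tapply(mark[idx], f, mean)),
    total_dna_intensity = as.numeric(tapply(dna[idx], f, sum)))
}

#' Segment bright repressive puncta within a nucleus
#'
#' Subtracts the nuclear background (the within-mask median, or the
#' histogram mode), clips at zero, Otsu-thresholds the residual over mask
#' voxels only, labels 3D components and drops any smaller than
#' `min_volume` (0.01 um^3 by default).
#'
#' @param masks A `nucleus_masks`.
#' @param mark Mark-channel array.
#' @param min_volume Minimum punctum volume, um^3.
#' @param background `"median"` (default) or `"mode"`.
#' @param nucleus Which nuclei to process (default all).
#' @param min_contrast Bright-puncta guard: the Otsu threshold must exceed
#'   `min_contrast` times the within-mask MAD of the residual, otherwise
#'   the nucleus is treated as punctum-free (prevents a unimodal noise
#'   floor from being split into spurious giant components).
#' @return Tibble with one row per punctum: `nucleus`, `punctum`, `volume`
#'   (um^3), `mean_intensity` (background-subtracted).
#' @export
segment_puncta <- function(masks, mark, min_volume = 0.01,
                           background = c("median", "mode"),
                           nucleus = NULL, min_contrast = 3) {
  stopifnot(inherits(masks, "nucleus_masks"))
  background <- match.arg(background)
  vvol <- prod(masks$voxel_size)
  dm <- dim(masks$labels)
  nuclei <- nucleus %||% seq_len(masks$n)
  out <- purrr::map(nuclei, function(nu) {
    inside <- masks$labels == nu
    if (!any(inside)) return(NULL)
    vals <- mark[inside]
    bg <- if (background == "median") median(vals) else hist_mode(vals)
    resid <- pmax(mark - bg, 0)
    resid[!inside] <- 0
    rv <- resid[inside]
    if (all(rv == 0)) return(NULL)
    thr <- otsu_threshold(rv)
    if (thr < min_contrast * stats::mad(mark[inside])) return(NULL)
    pm <- resid > thr & inside
    if (!any(pm)) return(NULL)
    lab <- array(cpp_label3(pm, dm), dm)
    k <- max(lab)
    sizes <- tabulate(lab[lab > 0], nbins = k)
    keep <- which(sizes * vvol >= min_volume)
    if (length(keep) == 0) return(NULL)
    mi <- tapply(resid[lab > 0], factor(lab[lab > 0], levels = keep), mean)
    tibble::tibble(nucleus = nu, punctum = seq_along(keep),
                   volume = sizes[keep] * vvol,
                   mean_intensity = as.numeric(mi))
  })
  res <- bind_rows(out)
  if (nrow(res) == 0)
    res <- tibble::tibble(nucleus = integer(), punctum = integer(),
                          volume = numeric(), mean_intensity = numeric())
  res
}

hist_mode <- function(x, n_bins = 128) {
  h <- hist(x, breaks = n_bins, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Radial intensity distribution within a nucleus
#'
#' Shells are built from the physical (anisotropic-aware) Euclidean
#' distance of each mask voxel to the mask boundary, cut into `n_shells`
#' equal-depth bins from the periphery (shell 1) to the centre. Each shell's
#' mean intensity is divided by the mean intensity of a cytoplasmic
#' reference region: by default a thin shell outside the nucleus, offset by
#' `ref_gap` voxels and `ref_thickness` voxels thick, excluding any other
#' nucleus.
#'
#' @param masks A `nucleus_masks`.
#' @param channel Intensity array.
#' @param n_shells Number of radial shells.
#' @param nucleus Nucleus label to profile.
#' @param reference Optional logical array marking the cytoplasmic
#'   reference region (overrides the automatic ring).
#' @param ref_gap,ref_thickness Ring construction, voxels.
#' @return Tibble of class `radial_profile`: `shell` (1 = periphery),
#'   `depth_lo`, `depth_hi` (um), `mean_intensity`, `ratio`
#'   (shell mean / cytoplasmic mean).
#' @export
radial_distribution <- function(masks, channel, n_shells = 10, nucleus = 1,
                                reference = NULL, ref_gap = 3,
                                ref_thickness = 2) {
  stopifnot(inherits(masks, "nucleus_masks"))
  dm <- dim(masks$labels)
  inside <- masks$labels == nucleus
  if (!any(inside)) abort("empty nucleus mask")
  depth <- array(cpp_edt3(inside, dm, masks$voxel_size), dm)
  if (is.null(reference)) {
    # distance (voxel units) from non-nucleus voxels to this nucleus
    dist_to_mask <- array(cpp_edt3(!inside, dm, rep(1, 3)), dm)
    reference <- masks$labels == 0 & dist_to_mask > ref_gap &
      dist_to_mask <= ref_gap + ref_thickness
  }
  if (!any(reference)) abort("empty cytoplasmic reference region")
  cyto <- mean(channel[reference])
  d <- depth[inside]
  edges <- seq(0, max(d) + 1e-9, length.out = n_shells + 1)
  bin <- as.integer(cut(d, edges, include.lowest = TRUE))  # 1 = periphery
  v <- channel[inside]
  out <- tibble::tibble(shell = seq_len(n_shells),
                        depth_lo = edges[-(n_shells + 1)],
                        depth_hi = edges[-1]) |>
    left_join(tibble::tibble(shell = bin, v = v) |>
                group_by(.data$shell) |>
                summarise(mean_intensity = mean(.data$v), .groups = "drop"),
              by = "shell") |>
    mutate(ratio = .data$mean_intensity / cyto)
  class(out) <- c("radial_profile", class(out))
  out
}
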