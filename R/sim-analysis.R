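#' H3K27me3 cluster decomposition of a frame
#'
#' Builds the contact graph on H3K27me3 beads (edge iff pairwise distance is
#' at most `contact_cutoff`) and takes connected components as clusters.
#' With `nucleoplasmic_only = TRUE`, clusters containing any currently
#' lamina-bonded bead are dropped, leaving the clusters diffusing in the
#' nucleoplasm.
#'
#' @param state A [sim_state()] (e.g. from [trajectory_frame()]).
#' @param contact_cutoff Contact distance, sigma. 1.5 (first-neighbour
#'   shell) by default; 2.5 (the interaction range) is the documented
#'   alternative.
#' @param nucleoplasmic_only Drop lamina-attached clusters?
#' @param method How "in the nucleoplasm" is decided: `"unbonded"` keeps
#'   clusters with no currently lamina-bonded member; `"interior"` keeps
#'   clusters whose centre of mass lies deeper than `interior_margin` below
#'   the confinement surface (the robust choice for small systems, where
#'   almost every large aggregate contains at least one bonded bead).
#' @param interior_margin Depth below the surface, sigma (for
#'   `method = "interior"`).
#' @return A list of class `cluster_stats`: `cluster_sizes` (beads),
#'   `mean_size`, `n_clusters`, `nucleoplasmic_only`, plus `membership`, a
#'   tibble mapping each H3K27me3 bead to its cluster (before filtering).
#' @export
identify_clusters <- function(state, contact_cutoff = 1.5,
                              nucleoplasmic_only = TRUE,
                              method = c("unbonded", "interior"),
                              interior_margin = 2) {
  stopifnot(inherits(state, "sim_state"))
  method <- match.arg(method)
  idx <- which(state$beads$h3k27me3)
  if (length(idx) == 0) {
    return(structure(list(cluster_sizes = integer(), mean_size = NA_real_,
                          n_clusters = 0L,
                          nucleoplasmic_only = nucleoplasmic_only,
                          membership = tibble::tibble(bead_index = integer(),
                                                      cluster = integer())),
                     class = "cluster_stats"))
  }
  pos <- state$positions[idx, , drop = FALSE]
  lab <- cpp_cluster_labels(pos, contact_cutoff)
  keep <- if (!nucleoplasmic_only) {
    unique(lab)
  } else if (method == "unbonded") {
    bonded <- state$bonds[idx] > 0
    setdiff(unique(lab), unique(lab[bonded]))
  } else {
    com_r <- vapply(split(seq_along(lab), lab), function(m)
      sqrt(sum(colMeans(pos[m, , drop = FALSE])^2)), numeric(1))
    as.integer(names(com_r))[com_r < state$radius - interior_margin]
  }
  sizes <- as.integer(table(factor(lab, levels = keep)))
  structure(list(cluster_sizes = sizes,
                 mean_size = if (length(sizes)) mean(sizes) else NA_real_,
                 n_clusters = length(sizes),
                 nucleoplasmic_only = nucleoplasmic_only,
                 membership = tibble::tibble(bead_index = idx, cluster = lab)),
            class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat("<cluster_stats> ", x$n_clusters, " clusters",
      if (x$nucleoplasmic_only) " (nucleoplasmic)", ", mean size ",
      round(x$mean_size, 2), " beads\n", sep = "")
  invisible(x)
}

#' Radial bead density profile
#'
#' Splits the confinement sphere into `n_shells` concentric shells of equal
#' thickness and reports per-shell bead density normalised to the mean
#' density over the whole sphere, so the volume-weighted mean of the profile
#' is exactly 1.
#'
#' @param state A [sim_state()].
#' @param n_shells Number of shells (>= 2).
#' @param subset Optional logical or integer index selecting beads (e.g.
#'   `state$beads$h3k27me3`).
#' @return Tibble of class `radial_profile`: `shell`, `r_lo`, `r_hi`
#'   (fractions of R), `count`, `density` (normalised).
#' @export
radial_density <- function(state, n_shells = 10, subset = NULL) {
  stopifnot(inherits(state, "sim_state"))
  if (n_shells < 2) abort("n_shells must be >= 2")
  pos <- state$positions
  if (!is.null(subset)) pos <- pos[subset, , drop = FALSE]
  R <- state$radius
  r <- sqrt(rowSums(pos^2)) / R
  edges <- seq(0, 1, length.out = n_shells + 1)
  counts <- as.integer(table(cut(pmin(r, 1), edges, include.lowest = TRUE)))
  vol <- diff(edges^3)  # shell volume as fraction of the sphere
  total <- sum(counts)
  density <- if (total > 0) (counts / vol) / total else rep(0, n_shells)
  out <- tibble::tibble(shell = seq_len(n_shells),
                        r_lo = edges[-(n_shells + 1)], r_hi = edges[-1],
                        count = counts, density = density)
  class(out) <- c("radial_profile", class(out))
  out
}

per_run_cluster_sizes <- function(traj, burn_in_fraction, contact_cutoff,
                                  method = "unbonded",
                                  interior_margin = 2) {
  nf <- length(traj$frames)
  first <- floor(burn_in_fraction * nf) + 1L
  frames <- first:nf
  vapply(frames, function(f) {
    cs <- identify_clusters(trajectory_frame(traj, f), contact_cutoff,
                            nucleoplasmic_only = TRUE, method = method,
                            interior_margin = interior_margin)
    if (cs$n_clusters == 0) NA_real_ else cs$mean_size
  }, numeric(1))
}

#' Compare lamina tether strengths
#'
#' For each run, computes the per-frame mean nucleoplasmic H3K27me3 cluster
#' size after burn-in and averages it into one summary value per run; the two
#' groups of run summaries (one trajectory each side also works, using frame
#' values as units) are compared with a one-sided Mann-Whitney test in the
#' direction of the observed difference. When the two sides hold equally many
#' runs launched from matched seeds, pairing by position (the Wilcoxon
#' signed-rank form) removes the seed-to-seed baseline variation and is used
#' automatically; set `paired = FALSE` to force the unpaired comparison.
#'
#' @param trajA,trajB A `chromatin_trajectory` or list of them (e.g. the
#'   strong- and weak-tether arms).
#' @param burn_in_fraction Fraction of initial frames discarded.
#' @param contact_cutoff Cluster contact distance, sigma.
#' @param method,interior_margin Nucleoplasm definition, see
#'   [identify_clusters()].
#' @param paired Pair runs by position (matched seeds)? Default: pair when
#'   both sides are run lists of the same length.
#' @return A list of class `tether_comparison`: `mean_A`, `mean_B`,
#'   `direction` (`"A larger"`, `"B larger"`, `"none"`), `p_value`,
#'   `paired`, `values_A`, `values_B`.
#' @export
compare_tether_strengths <- function(trajA, trajB, burn_in_fraction = 0.5,
                                     contact_cutoff = 1.5,
                                     method = c("unbonded", "interior"),
                                     interior_margin = 2, paired = NULL) {
  method <- match.arg(method)
  as_list <- function(x) if (inherits(x, "chromatin_trajectory")) list(x) else x
  la <- as_list(trajA); lb <- as_list(trajB)
  summarise_runs <- function(l) {
    if (length(l) == 1) {
      v <- per_run_cluster_sizes(l[[1]], burn_in_fraction, contact_cutoff,
                                 method, interior_margin)
    } else {
      v <- vapply(l, function(t)
        mean(per_run_cluster_sizes(t, burn_in_fraction, contact_cutoff,
                                   method, interior_margin),
             na.rm = TRUE), numeric(1))
    }
    v[is.finite(v)]
  }
  a <- summarise_runs(la); b <- summarise_runs(lb)
  if (length(a) < 2 || length(b) < 2)
    abort("insufficient frames/runs after burn-in for a rank test")
  paired <- paired %||%
    (length(la) > 1 && length(lb) > 1 && length(a) == length(b))
  dir <- if (mean(b) > mean(a)) "B larger" else if (mean(a) > mean(b)) "A larger" else "none"
  alt <- if (dir == "A larger") "greater" else "less"
  p <- suppressWarnings(wilcox.test(a, b, alternative = alt, paired = paired,
                                    exact = FALSE)$p.value)
  structure(list(mean_A = mean(a), mean_B = mean(b), direction = dir,
                 p_value = p, paired = paired, values_A = a, values_B = b),
            class = "tether_comparison")
}

#' @export
print.tether_comparison <- function(x, ...) {
  cat("<tether_comparison> mean cluster size A = ", round(x$mean_A, 2),
      ", B = ", round(x$mean_B, 2), "; ", x$direction,
      " (one-sided Mann-Whitney p = ", signif(x$p_value, 3), ")\n", sep = "")
  invisible(x)
}

#' @rdname compare_tether_strengths
#' @param x A `tether_comparison`.
#' @param ... Unused.
#' @export
tidy.tether_comparison <- function(x, ...) {
  tibble::tibble(mean_A = x$mean_A, mean_B = x$mean_B,
                 direction = x$direction, p_value = x$p_value,
                 paired = x$paired,
                 n_A = length(x$values_A), n_B = length(x$values_B))
}

#' Plot a radial density profile
#'
#' @param object A `radial_profile` tibble from [radial_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, ...) {
  mid <- (object$r_lo + object$r_hi) / 2
  ggplot2::ggplot(object, ggplot2::aes(x = mid, y = .data$density)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "radial position r/R", y = "normalised density")
}
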