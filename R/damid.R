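#' Filter a gene occupancy table
#'
#' Keeps genes confidently detected by the DamID pipeline: per-sample FDR
#' strictly below `fdr_threshold` and more than `gatc_min` GATC sites.
#'
#' @param table Gene occupancy tibble with columns `fdr` and `n_gatc` (see
#'   [read_occupancy_tsv()] for the full schema).
#' @param fdr_threshold Per-sample FDR cut-off (strict `<`).
#' @param gatc_min Minimum GATC site count (strict `>`).
#' @return The filtered tibble; warns if nothing survives.
#' @export
filter_genes <- function(table, fdr_threshold = 0.05, gatc_min = 1) {
  out <- dplyr::filter(table, .data$fdr < fdr_threshold,
                       .data$n_gatc > gatc_min)
  if (nrow(out) == 0 && nrow(table) > 0)
    warn("no genes pass the FDR/GATC filters")
  out
}

occupancy_means <- function(table) {
  ctrl_cols <- grep("^occ_ctrl", names(table), value = TRUE)
  mut_cols <- grep("^occ_mut", names(table), value = TRUE)
  if (length(ctrl_cols) > 0 && length(mut_cols) > 0) {
    list(ctrl = rowMeans(as.matrix(table[ctrl_cols])),
         mut = rowMeans(as.matrix(table[mut_cols])))
  } else if (all(c("mean_occupancy_control", "mean_occupancy_mutant") %in%
                 names(table))) {
    list(ctrl = table$mean_occupancy_control,
         mut = table$mean_occupancy_mutant)
  } else {
    abort("table needs occ_ctrl_*/occ_mut_* replicate columns or mean_occupancy_{control,mutant}")
  }
}

#' PCA-regression differential-occupancy hit calling
#'
#' Forms one 2D point per gene from the replicate-mean occupancies
#' (control, mutant), takes the first principal axis of the centred cloud as
#' the regression line, and scores each gene by its signed projection onto
#' the second principal axis, standardised by the projection standard
#' deviation (`z_pca`). The sign is oriented so that mutant-enriched genes
#' (the paper's "below the regression line" side) get positive z. A gene is
#' significant when `|z| > z_threshold`, its FDR passes `fdr_threshold` and
#' it has more than `gatc_min` GATC sites.
#'
#' @param table Filtered occupancy tibble (>= 3 genes).
#' @param z_threshold Two-tailed z cut-off (1.96, approximately a 95%
#'   confidence band).
#' @param fdr_threshold,gatc_min Re-applied per-gene cut-offs (the
#'   significance flag requires all three criteria).
#' @return Tibble of class `damid_hits`: input identifier columns plus
#'   `mean_ctrl`, `mean_mut`, `z_pca`, `direction`
#'   (`"increased"`/`"decreased"` in the mutant), `significant`.
#' @export
pca_regression_hits <- function(table, z_threshold = 1.96,
                                fdr_threshold = 0.05, gatc_min = 1) {
  if (nrow(table) < 3) abort("need at least 3 genes for PCA regression")
  m <- occupancy_means(table)
  pts <- cbind(m$ctrl, m$mut)
  if (sd(pts[, 1]) == 0 && sd(pts[, 2]) == 0)
    abort("degenerate point cloud: zero variance")
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < 2 || pc$sdev[2] <= 1e-12 * pc$sdev[1])
    abort("degenerate point cloud: all points on a single line")
  v2 <- pc$rotation[, 2]
  # orient: positive score = mutant side of the line
  if (v2[2] < 0 || (v2[2] == 0 && v2[1] > 0)) v2 <- -v2
  s <- sweep(pts, 2, pc$center) %*% v2
  z <- drop(s) / sd(s)
  out <- table
  out$mean_ctrl <- m$ctrl
  out$mean_mut <- m$mut
  out$z_pca <- z
  out$direction <- ifelse(z > 0, "increased", "decreased")
  out$significant <- abs(z) > z_threshold & out$fdr < fdr_threshold &
    out$n_gatc > gatc_min
  class(out) <- c("damid_hits", class(out))
  out
}

#' Percent overlap between two hit sets
#'
#' Defaults to the Jaccard form, `|A intersect B| / |A union B|`, as a
#' percentage; `denominator = "min"` divides by the smaller set instead.
#'
#' @param hitsA,hitsB Character vectors of gene ids.
#' @param denominator `"union"` (default) or `"min"`.
#' @return Percent overlap (0 when both sets are empty).
#' @export
group_overlap <- function(hitsA, hitsB, denominator = c("union", "min")) {
  denominator <- match.arg(denominator)
  a <- unique(hitsA); b <- unique(hitsB)
  if (length(a) == 0 && length(b) == 0) return(0)
  num <- length(intersect(a, b))
  den <- if (denominator == "union") length(union(a, b))
         else min(length(a), length(b))
  if (den == 0) return(0)
  100 * num / den
}

#' Cluster per-gene fold changes with k-means and the Gap statistic
#'
#' Runs k-means for k = 1..`k_max` on the genes x factors fold-change matrix
#' (missing entries count as 0 fold change, i.e. no evidence of change) and
#' picks k with the Gap statistic against a uniform-box reference, using the
#' standard one-standard-error rule.
#'
#' @param fold_changes Numeric matrix or data frame, genes in rows (row
#'   names or a `gene_id` column as identifiers), one column per factor;
#'   may contain NA.
#' @param k_max Maximum number of clusters considered.
#' @param B Number of Gap reference datasets.
#' @param seed Integer seed (k-means starts and reference draws).
#' @return A list of class `fold_change_clusters`: `labels` (tibble
#'   `gene_id`, `cluster`), `k`, `gap` (per-k Gap table), `centers`.
#' @export
cluster_fold_changes <- function(fold_changes, k_max = 6, B = 50, seed = 1) {
  df <- as.data.frame(fold_changes)
  ids <- if ("gene_id" %in% names(df)) {
    out <- df$gene_id
    df$gene_id <- NULL
    out
  } else rownames(df) %||% as.character(seq_len(nrow(df)))
  x <- as.matrix(df)
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing)) {
    warn(paste(sum(all_missing), "all-missing rows dropped"))
    x <- x[!all_missing, , drop = FALSE]
    ids <- ids[!all_missing]
  }
  x[is.na(x)] <- 0
  if (nrow(x) < 2 * k_max) abort("need at least 2 * k_max genes")
  km <- function(x, k) kmeans(x, k, nstart = 10, iter.max = 50)
  withr::with_seed(as.integer(seed), {
    gap <- cluster::clusGap(x, FUNcluster = km, K.max = k_max, B = B,
                            verbose = FALSE)
    k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                        method = "Tibs2001SEmax")
    fit <- km(x, k)
  })
  structure(list(labels = tibble::tibble(gene_id = ids,
                                         cluster = fit$cluster),
                 k = k,
                 gap = tibble::as_tibble(gap$Tab) |>
                   mutate(k = dplyr::row_number(), .before = 1),
                 centers = fit$centers),
            class = "fold_change_clusters")
}

#' @export
print.fold_change_clusters <- function(x, ...) {
  cat("<fold_change_clusters> k =", x$k, "clusters over",
      nrow(x$labels), "genes\n")
  invisible(x)
}

#' @rdname cluster_fold_changes
#' @param x A `fold_change_clusters`.
#' @param ... Unused.
#' @export
tidy.fold_change_clusters <- function(x, ...) x$labels

#' Plot PCA-regression hit calls
#'
#' Mutant vs control mean occupancy, significant genes highlighted.
#'
#' @param object A `damid_hits` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.damid_hits <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_ctrl, y = .data$mean_mut,
                               colour = ifelse(.data$significant,
                                               .data$direction, "ns"))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(increased = "#c0392b", decreased = "#2980b9", ns = "grey70"),
      name = NULL) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::labs(x = "mean occupancy, control (log2)",
                  y = "mean occupancy, mutant (log2)")
}
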