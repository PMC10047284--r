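#' Synthetic DamID cohort specification
#'
#' Describes a replicate-structured per-gene occupancy dataset with a known
#' minority of truly differential genes. Baseline log2 occupancies are
#' standard normal; replicates add Gaussian noise; true hits shift the
#' mutant baseline by `effect_size`. Per-sample FDR emulates occupancy
#' confidence (not differential evidence): true hits are always confidently
#' detected (`fdr < hit_fdr_max`, `n_gatc >= hit_gatc_min`), other genes
#' draw FDR uniformly on (0, `null_fdr_max`) — per-gene tables are
#' dominated by confidently occupied genes, so most survive the FDR filter
#' — and GATC counts uniformly over `gatc_range`.
#'
#' @param n_genes Number of genes.
#' @param n_true_hits Number of truly differential genes.
#' @param effect_size Mutant shift for true hits, log2 units.
#' @param frac_up Fraction of true hits shifted upward (the rest get the
#'   negative shift).
#' @param replicate_sd Per-replicate noise, log2 units.
#' @param n_replicates Replicates per condition.
#' @param hit_fdr_max Upper bound of the FDR draw for true hits.
#' @param null_fdr_max Upper bound of the FDR draw for non-hit genes.
#' @param gatc_range Integer range of GATC counts for non-hit genes.
#' @param hit_gatc_min Minimum GATC count for true hits.
#' @param chrom_lengths Named chromosome lengths, bp.
#' @param gene_length Gene body length, bp.
#' @param clustering `"none"` (hits uniform) or `"clustered"` (hits placed
#'   in tight blocks within `cluster_window`).
#' @param cluster_window Intra-block gene spacing bound, bp.
#' @param cluster_size Genes per hit block in clustered mode.
#' @return A list of class `synth_damid_spec`.
#' @export
synth_damid_spec <- function(n_genes = 5000, n_true_hits = 50,
                             effect_size = 1.5, frac_up = 1,
                             replicate_sd = 0.2, n_replicates = 3,
                             hit_fdr_max = 0.04, null_fdr_max = 0.25,
                             gatc_range = c(1L, 20L),
                             hit_gatc_min = 2L,
                             chrom_lengths = c(chr2L = 23.5e6,
                                               chr2R = 25.3e6,
                                               chr3L = 28.1e6,
                                               chr3R = 32.1e6),
                             gene_length = 2000,
                             clustering = c("none", "clustered"),
                             cluster_window = 10000, cluster_size = 4) {
  clustering <- match.arg(clustering)
  if (n_true_hits > n_genes) abort("n_true_hits must be <= n_genes")
  if (!is.finite(effect_size)) abort("effect_size must be finite")
  structure(as.list(environment()), class = "synth_damid_spec")
}

#' Generate a non-overlapping gene annotation
#'
#' Gene counts are apportioned to chromosomes proportionally to length;
#' within a chromosome, starts are drawn by the uniform-spacings
#' construction, which guarantees non-overlap of the fixed-length gene
#' bodies.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths, bp.
#' @param n_genes Total gene count.
#' @param seed Integer seed.
#' @param gene_length Gene body length, bp.
#' @return Sorted annotation tibble: `chrom`, `start`, `end`, `gene_id`,
#'   `score`, `strand` (0-based half-open).
#' @export
gen_annotation <- function(chrom_lengths, n_genes, seed,
                           gene_length = 2000) {
  if (n_genes == 0)
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), gene_id = character(),
                          score = numeric(), strand = character()))
  per <- apportion(n_genes, chrom_lengths / sum(chrom_lengths))
  withr::with_seed(as.integer(seed), {
    parts <- purrr::map2(names(chrom_lengths), per, function(ch, k) {
      if (k == 0) return(NULL)
      L <- chrom_lengths[[ch]]
      if (k * gene_length > L)
        abort(paste("cannot place", k, "genes of", gene_length, "bp on", ch))
      starts <- floor(sort(runif(k)) * (L - k * gene_length)) +
        (seq_len(k) - 1) * gene_length
      tibble::tibble(chrom = ch, start = starts,
                     end = starts + gene_length)
    })
  })
  ann <- bind_rows(parts)
  ann$gene_id <- sprintf("g%05d", seq_len(nrow(ann)))
  ann$score <- 0
  ann$strand <- "+"
  ann
}

apportion <- function(n, fr) {
  k <- floor(fr * n)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(fr * n - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

#' Generate a synthetic DamID gene occupancy table
#'
#' @param spec A [synth_damid_spec()].
#' @param seed Integer seed; the output is a pure function of
#'   `(spec, seed)`.
#' @return A list of class `synth_damid`: `table` (occupancy tibble in the
#'   [read_occupancy_tsv()] schema) and `truth` (`gene_id`, `is_hit`,
#'   `effect`).
#' @export
gen_damid_table <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_damid_spec"))
  if (spec$clustering == "clustered" &&
      spec$cluster_window > min(spec$chrom_lengths))
    abort("cluster_window larger than the smallest chromosome")
  withr::with_seed(as.integer(seed), {
    ann_seed <- sample.int(.Machine$integer.max, 1)
    ann <- gen_annotation(spec$chrom_lengths, spec$n_genes, ann_seed,
                          spec$gene_length)
    n <- nrow(ann)
    if (spec$clustering == "none") {
      hit_idx <- sample.int(n, spec$n_true_hits)
    } else {
      placed <- place_clustered_hits(ann, spec)
      ann <- placed$ann
      hit_idx <- placed$hit_idx
    }
    is_hit <- seq_len(n) %in% hit_idx
    sign <- ifelse(runif(n) < spec$frac_up, 1, -1)
    effect <- ifelse(is_hit, sign * spec$effect_size, 0)

    baseline <- rnorm(n)
    reps <- spec$n_replicates
    ctrl <- matrix(baseline, n, reps) +
      matrix(rnorm(n * reps, sd = spec$replicate_sd), n, reps)
    mut <- matrix(baseline + effect, n, reps) +
      matrix(rnorm(n * reps, sd = spec$replicate_sd), n, reps)
    colnames(ctrl) <- paste0("occ_ctrl_rep", seq_len(reps))
    colnames(mut) <- paste0("occ_mut_rep", seq_len(reps))

    fdr <- ifelse(is_hit, runif(n) * spec$hit_fdr_max,
                  runif(n) * spec$null_fdr_max)
    g <- spec$gatc_range
    n_gatc <- sample(g[1]:g[2], n, replace = TRUE)
    n_gatc[is_hit] <- pmax(n_gatc[is_hit], spec$hit_gatc_min)
  })
  table <- dplyr::bind_cols(
    ann[c("gene_id", "chrom", "start", "end")],
    tibble::as_tibble(ctrl), tibble::as_tibble(mut),
    tibble::tibble(fdr = fdr, n_gatc = as.integer(n_gatc)))
  structure(list(table = table,
                 truth = tibble::tibble(gene_id = ann$gene_id,
                                        is_hit = is_hit, effect = effect)),
            class = "synth_damid")
}

# pick blocks of consecutive annotation genes and squeeze their spacing so
# each block sits within the cluster window; returns hit row indices
place_clustered_hits <- function(ann, spec) {
  n <- nrow(ann)
  n_blocks <- ceiling(spec$n_true_hits / spec$cluster_size)
  # candidate block anchors: genes with enough same-chromosome followers
  anchors <- integer(0)
  taken <- rep(FALSE, n)
  tries <- 0
  while (length(anchors) < n_blocks && tries < 50 * n_blocks) {
    tries <- tries + 1
    a <- sample.int(n - spec$cluster_size, 1)
    rows <- a:(a + spec$cluster_size - 1)
    if (length(unique(ann$chrom[rows])) > 1 || any(taken[rows])) next
    anchors <- c(anchors, a)
    taken[rows] <- TRUE
  }
  if (length(anchors) < n_blocks)
    abort("failed to place clustered hit blocks")
  hit_idx <- integer(0)
  for (a in anchors) {
    rows <- a:(a + spec$cluster_size - 1)
    # compact the block: successive gaps drawn within half the window
    gaps <- runif(spec$cluster_size - 1, 0, spec$cluster_window / 2)
    len <- ann$end[rows] - ann$start[rows]
    for (j in seq_along(rows)[-1]) {
      s_next <- ann$end[rows[j - 1]] + gaps[j - 1]
      ann$start[rows[j]] <- s_next
      ann$end[rows[j]] <- s_next + len[j]
    }
    hit_idx <- c(hit_idx, rows)
  }
  list(ann = ann, hit_idx = hit_idx[seq_len(spec$n_true_hits)])
}
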