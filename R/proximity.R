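#' Count genes with a nearby neighbour in the same set
#'
#' A gene counts as "near" when its closest other gene in the set, on the
#' same chromosome, lies within `window`. Distance between gene bodies is
#' the interval gap `max(0, later.start - earlier.end)` (0 for overlapping
#' genes); `distance = "midpoint"` uses midpoint-to-midpoint distance
#' instead.
#'
#' @param genes Tibble with `chrom`, `start`, `end` (0-based half-open bp).
#' @param window Distance threshold, bp (strict `<`).
#' @param distance `"gap"` (default) or `"midpoint"`.
#' @return Integer count of genes with a near neighbour.
#' @export
count_proximal_genes <- function(genes, window = 10000,
                                 distance = c("gap", "midpoint")) {
  distance <- match.arg(distance)
  sum(nearest_neighbor_distance(genes$chrom, genes$start, genes$end,
                                distance) < window)
}

# Per-gene distance to the nearest other gene on the same chromosome
# (Inf when alone). Uses sorted adjacency when intervals do not overlap
# within a chromosome; falls back to IRanges otherwise.
nearest_neighbor_distance <- function(chrom, start, end, distance = "gap") {
  n <- length(start)
  out <- rep(Inf, n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    if (length(idx) < 2) next
    if (distance == "midpoint") {
      mid <- (start[idx] + end[idx]) / 2
      ord <- order(mid)
      d <- diff(mid[ord])
      nd <- pmin(c(Inf, d), c(d, Inf))
      out[idx[ord]] <- nd
    } else {
      ord <- order(start[idx], end[idx])
      s <- start[idx][ord]; e <- end[idx][ord]
      if (all(s[-1] >= cummax(e[-length(e)]))) {
        gaps <- pmax(0, s[-1] - e[-length(e)])
        out[idx[ord]] <- pmin(c(Inf, gaps), c(gaps, Inf))
      } else {
        # overlapping annotation: exact nearest-range distance
        ir <- IRanges::IRanges(start = start[idx] + 1L, end = end[idx])
        hit <- IRanges::distanceToNearest(ir)
        d <- rep(Inf, length(idx))
        d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
        out[idx] <- d
      }
    }
  }
  out
}

#' Monte-Carlo test of gene clustering along chromosomes
#'
#' Tests whether a hit set sits closer together along the genome than random
#' gene sets of the same size. The observed statistic is the number of hit
#' genes whose nearest other hit lies within `window`
#' ([count_proximal_genes()]). The null redraws `|hits|` genes uniformly
#' without replacement from the annotation restricted to the allowed
#' chromosome arms, `nruns` times; the p-value is `(NGE + 1) / (nruns + 1)`
#' with NGE the number of null draws reaching at least the observed count.
#'
#' @param hits Character vector of hit gene ids (must appear in
#'   `annotation`) or a tibble with a `gene_id` column.
#' @param annotation Gene annotation tibble: `chrom`, `start`, `end`,
#'   `gene_id` (0-based half-open; see [read_gene_bed()]).
#' @param window Proximity window, bp.
#' @param nruns Number of Monte-Carlo draws.
#' @param seed Integer seed.
#' @param distance Gene-gene distance definition, `"gap"` or `"midpoint"`.
#' @param chromosomes Chromosome arms the null draws from (the fly autosome
#'   arms by default); hits outside them are rejected.
#' @return A list of class `proximity_test`: `observed_count`,
#'   `null_counts`, `null_median`, `p_value`, `n_hits`, `window`.
#' @export
proximity_mc_test <- function(hits, annotation, window = 10000, nruns = 1000,
                              seed = 1, distance = c("gap", "midpoint"),
                              chromosomes = c("chr2L", "chr2R",
                                              "chr3L", "chr3R")) {
  distance <- match.arg(distance)
  if (is.data.frame(hits)) hits <- hits$gene_id
  ann <- dplyr::filter(annotation, .data$chrom %in% chromosomes)
  if (!all(hits %in% ann$gene_id))
    abort("all hits must be annotation genes on the allowed chromosomes")
  n_hits <- length(unique(hits))
  if (n_hits > nrow(ann)) abort("more hits than annotation genes")

  hit_rows <- ann[match(unique(hits), ann$gene_id), ]
  observed <- count_proximal_genes(hit_rows, window, distance)

  chrom <- ann$chrom; start <- ann$start; end <- ann$end
  null_counts <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(nruns), function(i) {
      pick <- sample.int(nrow(ann), n_hits)
      sum(nearest_neighbor_distance(chrom[pick], start[pick], end[pick],
                                    distance) < window)
    }, numeric(1))
  })
  nge <- sum(null_counts >= observed)
  structure(list(observed_count = observed,
                 null_counts = as.integer(null_counts),
                 null_median = median(null_counts),
                 p_value = (nge + 1) / (nruns + 1),
                 n_hits = n_hits, window = window),
            class = "proximity_test")
}

#' @export
print.proximity_test <- function(x, ...) {
  cat("<proximity_test> ", x$observed_count, " of ", x$n_hits,
      " hit genes within ", x$window, " bp of another hit",
      " (null median ", x$null_median, ", p = ", signif(x$p_value, 3), ")\n",
      sep = "")
  invisible(x)
}

#' @rdname proximity_mc_test
#' @param x A `proximity_test`.
#' @param ... Unused.
#' @export
tidy.proximity_test <- function(x, ...) {
  tibble::tibble(observed_count = x$observed_count,
                 null_median = x$null_median, p_value = x$p_value,
                 n_hits = x$n_hits, window = x$window,
                 nruns = length(x$null_counts))
}
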