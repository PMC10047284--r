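#' Coarse-grained genome specification
#'
#' Parameters of the bead-level genome model: one bead represents a fixed
#' window of DNA (5 kb by default, a 30 nm bead), the genome is split into a
#' small number of chromosome chains, each carrying a pericentromeric
#' heterochromatin (PCH) block, and H3K27me3 is laid down as random
#' exponential-length patches up to a target coverage.
#'
#' The default coverage target (40% of beads) is enforced globally along the
#' genome. An alternative mode (`coverage_mode = "per_compartment"`) targets
#' euchromatin and PCH separately (22% and 77.5% by default); the two
#' compartment coverages compose to about 38.7% of the genome, slightly below
#' the global 40% target, which is why the two modes are kept distinct.
#'
#' @param genome_length_bp Total genome length in base pairs.
#' @param bp_per_bead DNA content of one bead, bp.
#' @param bead_diameter_nm Physical bead diameter, nm (bookkeeping only; all
#'   simulation lengths are in bead-diameter units, sigma).
#' @param n_chromosomes Number of chromosome chains.
#' @param frac_euchromatin,frac_pch Euchromatin / PCH bead fractions; must sum
#'   to 1.
#' @param h3k27me3_target_coverage Global H3K27me3 coverage target (fraction
#'   of beads).
#' @param mean_patch_len_beads Mean of the exponential patch-length
#'   distribution, beads.
#' @param eu_h3k27me3_coverage,pch_h3k27me3_coverage Per-compartment coverage
#'   targets used when `coverage_mode = "per_compartment"`.
#' @param coverage_mode `"global"` (default) or `"per_compartment"`.
#' @param chrom_fractions Optional numeric vector of length `n_chromosomes`
#'   giving relative chromosome lengths (normalised internally); equal by
#'   default.
#' @param pch_position Where the PCH block sits in each chain: `"center"`
#'   (default, pericentromeric) or `"end"`.
#' @return A list of class `genome_spec`.
#' @examples
#' spec <- genome_spec()
#' compute_bead_count(spec$genome_length_bp, spec$bp_per_bead)
#' @export
genome_spec <- function(genome_length_bp = 176.2e6,
                        bp_per_bead = 5000,
                        bead_diameter_nm = 30,
                        n_chromosomes = 4,
                        frac_euchromatin = 0.70,
                        frac_pch = 0.30,
                        h3k27me3_target_coverage = 0.40,
                        mean_patch_len_beads = 17,
                        eu_h3k27me3_coverage = 0.22,
                        pch_h3k27me3_coverage = 0.775,
                        coverage_mode = c("global", "per_compartment"),
                        chrom_fractions = NULL,
                        pch_position = c("center", "end")) {
  coverage_mode <- match.arg(coverage_mode)
  pch_position <- match.arg(pch_position)
  if (genome_length_bp <= 0 || bp_per_bead <= 0)
    abort("genome_length_bp and bp_per_bead must be positive")
  if (abs(frac_euchromatin + frac_pch - 1) > 1e-9)
    abort("frac_euchromatin + frac_pch must equal 1")
  if (frac_pch < 0 || frac_pch > 1)
    abort("compartment fractions must lie in [0, 1]")
  if (h3k27me3_target_coverage < 0 || h3k27me3_target_coverage >= 1)
    abort("h3k27me3_target_coverage must lie in [0, 1)")
  if (mean_patch_len_beads < 1)
    abort("mean_patch_len_beads must be >= 1")
  if (!is.null(chrom_fractions)) {
    if (length(chrom_fractions) != n_chromosomes || any(chrom_fractions <= 0))
      abort("chrom_fractions must be ", n_chromosomes, " positive values")
    chrom_fractions <- chrom_fractions / sum(chrom_fractions)
  }
  structure(
    list(genome_length_bp = genome_length_bp, bp_per_bead = bp_per_bead,
         bead_diameter_nm = bead_diameter_nm, n_chromosomes = n_chromosomes,
         frac_euchromatin = frac_euchromatin, frac_pch = frac_pch,
         h3k27me3_target_coverage = h3k27me3_target_coverage,
         mean_patch_len_beads = mean_patch_len_beads,
         eu_h3k27me3_coverage = eu_h3k27me3_coverage,
         pch_h3k27me3_coverage = pch_h3k27me3_coverage,
         coverage_mode = coverage_mode, chrom_fractions = chrom_fractions,
         pch_position = pch_position),
    class = "genome_spec")
}

#' Number of beads representing a genome
#'
#' @param genome_length_bp Genome length, bp.
#' @param bp_per_bead DNA per bead, bp.
#' @return Integer bead count, `round(genome_length_bp / bp_per_bead)`.
#' @examples
#' compute_bead_count(176.2e6, 5000) # 35240
#' @export
compute_bead_count <- function(genome_length_bp, bp_per_bead) {
  if (!is.numeric(genome_length_bp) || !is.numeric(bp_per_bead) ||
      genome_length_bp <= 0 || bp_per_bead <= 0)
    abort("genome_length_bp and bp_per_bead must be positive numbers")
  n <- as.integer(round(genome_length_bp / bp_per_bead))
  max(n, 1L)
}

#' Partition beads into chromosomes and compartments
#'
#' Splits `n_beads` into contiguous chromosome chains (equal lengths by
#' default, remainder on the last chain) and assigns each chain a single
#' contiguous PCH block containing its share of the genome-wide PCH bead
#' count, centred at the chain midpoint (or at the chain end, per the spec's
#' `pch_position`). All other beads are euchromatic.
#'
#' @param spec A [genome_spec()].
#' @param n_beads Total bead count; defaults to the count implied by `spec`.
#' @return A tibble with one row per bead: `bead_index` (1-based),
#'   `chromosome`, `compartment` (`"EU"`/`"PCH"`), `h3k27me3` (all `FALSE`).
#' @examples
#' beads <- partition_genome(genome_spec(), n_beads = 400)
#' table(beads$compartment)
#' @export
partition_genome <- function(spec, n_beads = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  if (is.null(n_beads))
    n_beads <- compute_bead_count(spec$genome_length_bp, spec$bp_per_bead)
  n_beads <- as.integer(n_beads)
  if (n_beads < spec$n_chromosomes)
    abort("n_beads must be >= n_chromosomes")

  k <- spec$n_chromosomes
  fr <- spec$chrom_fractions %||% rep(1 / k, k)
  len <- floor(fr * n_beads)
  len[k] <- n_beads - sum(len[-k])  # remainder to last chain

  # exact genome-wide PCH count, apportioned by largest remainder
  total_pch <- round(spec$frac_pch * n_beads)
  quota <- spec$frac_pch * len * (total_pch / max(1, sum(spec$frac_pch * len)))
  pch_len <- floor(quota)
  rem <- total_pch - sum(pch_len)
  if (rem > 0) {
    ord <- order(quota - pch_len, decreasing = TRUE)
    pch_len[ord[seq_len(rem)]] <- pch_len[ord[seq_len(rem)]] + 1L
  }
  pch_len <- pmin(pch_len, len)

  chrom <- rep.int(seq_len(k), len)
  comp <- rep("EU", n_beads)
  offset <- c(0L, cumsum(len))
  for (i in seq_len(k)) {
    if (pch_len[i] == 0) next
    if (spec$pch_position == "center") {
      s <- offset[i] + floor((len[i] - pch_len[i]) / 2) + 1L
    } else {
      s <- offset[i] + len[i] - pch_len[i] + 1L
    }
    comp[s:(s + pch_len[i] - 1L)] <- "PCH"
  }

  tibble::tibble(
    bead_index = seq_len(n_beads),
    chromosome = chrom,
    compartment = comp,
    h3k27me3 = FALSE)
}

#' Chromosome bounds of a bead table
#'
#' @param beads A bead tibble from [partition_genome()].
#' @return Tibble with `chromosome`, `start`, `end` (1-based inclusive bead
#'   indices).
#' @export
chromosome_bounds <- function(beads) {
  beads |>
    group_by(.data$chromosome) |>
    summarise(start = min(.data$bead_index), end = max(.data$bead_index),
              .groups = "drop")
}

#' Lay down H3K27me3 patches by rejection Monte Carlo
#'
#' Repeatedly draws a patch length from a discretised exponential
#' distribution (continuous draw rounded, floored at 1 bead) and a uniform
#' start bead, rejecting any candidate that would overlap an existing patch
#' or cross a chromosome boundary, until the flagged fraction first reaches
#' the coverage target. The final accepted patch may overshoot the target by
#' less than its own length. With `coverage_mode = "per_compartment"` the
#' same sampler runs with per-compartment targets and candidate patches must
#' also stay within one compartment.
#'
#' @param beads Bead tibble from [partition_genome()] with no flags set.
#' @param spec The [genome_spec()].
#' @param seed Integer seed; the result is a pure function of
#'   `(beads, spec, seed)`.
#' @return The bead tibble with `h3k27me3` filled in; the accepted patches
#'   (start, length, chromosome) are attached as attribute `"patches"`.
#' @examples
#' spec <- genome_spec()
#' beads <- partition_genome(spec, n_beads = 2000)
#' beads <- generate_h3k27me3_patches(beads, spec, seed = 1)
#' mean(beads$h3k27me3)
#' @export
generate_h3k27me3_patches <- function(beads, spec, seed) {
  stopifnot(inherits(spec, "genome_spec"))
  if (any(beads$h3k27me3))
    abort("beads already carry H3K27me3 flags")
  n <- nrow(beads)
  withr::with_seed(as.integer(seed), {
    if (spec$coverage_mode == "global") {
      if (spec$h3k27me3_target_coverage >= 0.95)
        abort("coverage targets >= 0.95 are outside the rejection sampler's terminating regime")
      res <- sample_patches(beads$chromosome, rep(TRUE, n),
                            target_n = spec$h3k27me3_target_coverage * n,
                            mean_len = spec$mean_patch_len_beads)
    } else {
      if (spec$eu_h3k27me3_coverage >= 0.95 || spec$pch_h3k27me3_coverage >= 0.95)
        abort("coverage targets >= 0.95 are outside the rejection sampler's terminating regime")
      eu <- beads$compartment == "EU"
      res_eu <- sample_patches(beads$chromosome, eu,
                               target_n = spec$eu_h3k27me3_coverage * sum(eu),
                               mean_len = spec$mean_patch_len_beads)
      res_pch <- sample_patches(beads$chromosome, !eu,
                                target_n = spec$pch_h3k27me3_coverage * sum(!eu),
                                mean_len = spec$mean_patch_len_beads,
                                flags = res_eu$flags, patches = res_eu$patches)
      res <- res_pch
    }
  })
  beads$h3k27me3 <- res$flags
  attr(beads, "patches") <- res$patches
  beads
}

# Rejection sampler over an eligibility mask. `target_n` counts newly flagged
# beads within `eligible`; pre-existing flags/patches may be carried through.
sample_patches <- function(chromosome, eligible, target_n, mean_len,
                           flags = NULL, patches = NULL) {
  n <- length(chromosome)
  flags <- flags %||% rep(FALSE, n)
  starts <- patches$start %||% integer()
  lens <- patches$length %||% integer()
  chroms <- patches$chromosome %||% integer()
  if (target_n <= 0)
    return(list(flags = flags,
                patches = tibble::tibble(start = starts, length = lens,
                                         chromosome = chroms)))
  flagged <- 0L
  max_draws <- 40L * ceiling(target_n / mean_len) + 2000L
  draws <- 0L
  while (flagged < target_n) {
    draws <- draws + 1L
    if (draws > max_draws)
      abort("patch sampler failed to reach the coverage target (too many rejections)")
    # keep the drawn length and retry only the position, so rejection does
    # not bias the accepted length distribution away from the stated mean
    len <- max(1L, as.integer(round(rexp(1, 1 / mean_len))))
    placed <- FALSE
    for (try in seq_len(1000L)) {
      s <- sample.int(n, 1L)
      e <- s + len - 1L
      if (e > n) next
      idx <- s:e
      if (chromosome[e] != chromosome[s]) next       # crosses a boundary
      if (!all(eligible[idx])) next                  # leaves the compartment
      if (any(flags[idx])) next                      # overlaps a patch
      flags[idx] <- TRUE
      flagged <- flagged + len
      starts <- c(starts, s); lens <- c(lens, len)
      chroms <- c(chroms, chromosome[s])
      placed <- TRUE
      break
    }
    if (!placed) next  # no room for this length; redraw
  }
  list(flags = flags,
       patches = tibble::tibble(start = starts, length = lens,
                                chromosome = chroms))
}

#' Summary statistics of H3K27me3 patches
#'
#' A patch is a maximal run of consecutively flagged beads (adjacent accepted
#' patches merge into one run). Coverage is the flagged fraction, reported
#' overall and per compartment.
#'
#' @param beads Bead tibble with an `h3k27me3` column.
#' @return One-row tibble: `n_patches`, `mean_len` (NA when no patch),
#'   `coverage`, `coverage_eu`, `coverage_pch`.
#' @export
patch_statistics <- function(beads) {
  f <- beads$h3k27me3
  r <- rle(f)
  runs <- r$lengths[r$values]
  frac <- function(x) if (length(x) == 0) 0 else mean(x)
  tibble::tibble(
    n_patches = length(runs),
    mean_len = if (length(runs) == 0) NA_real_ else mean(runs),
    coverage = frac(f),
    coverage_eu = frac(f[beads$compartment == "EU"]),
    coverage_pch = frac(f[beads$compartment == "PCH"]))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", format(x$genome_length_bp, big.mark = ","), " bp, ",
      x$bp_per_bead, " bp/bead (",
      compute_bead_count(x$genome_length_bp, x$bp_per_bead), " beads), ",
      x$n_chromosomes, " chromosomes\n", sep = "")
  cat("  EU/PCH: ", x$frac_euchromatin, "/", x$frac_pch,
      "; H3K27me3 target ", x$h3k27me3_target_coverage,
      " (", x$coverage_mode, "), mean patch ",
      x$mean_patch_len_beads, " beads\n", sep = "")
  invisible(x)
}
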