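#' Quantify a synthetic cohort end-to-end
#'
#' Runs every stack of a cohort through [segment_nuclei()] and
#' [quantify_nuclei()] and joins the per-nucleus measures to the sample
#' hierarchy, giving the table [compare_groups()] consumes.
#'
#' @param cohort A `synth_nuclei` cohort (in memory).
#' @param sigma,min_volume Segmentation settings, see [segment_nuclei()].
#' @return Tibble: `stack`, `genotype`, `larva_id`, `muscle_id`,
#'   `nucleus_id`, `volume`, `mean_mark_intensity`, `total_dna_intensity`.
#'   Stacks where segmentation finds no nucleus are dropped.
#' @export
quantify_cohort <- function(cohort, sigma = 1, min_volume = 20) {
  stopifnot(inherits(cohort, "synth_nuclei"))
  rows <- purrr::map(seq_along(cohort$stacks), function(i) {
    st <- cohort$stacks[[i]]
    masks <- suppressWarnings(
      segment_nuclei(st$dna, st$voxel_size, sigma = sigma,
                     min_volume = min_volume))
    if (masks$n == 0) return(NULL)
    q <- quantify_nuclei(masks, st$dna, st$mark)
    # one nucleus per synthetic stack: keep the largest component
    q <- q[which.max(q$volume), ]
    q$stack <- i
    q
  })
  bind_rows(rows) |>
    left_join(cohort$samples, by = "stack") |>
    select("stack", "genotype", "larva_id", "muscle_id", "nucleus_id",
           "volume", "mean_mark_intensity", "total_dna_intensity")
}

#' Recover an injected genotype intensity effect
#'
#' Generates a cohort with the given spec, quantifies it with the image
#' pipeline and estimates the genotype effect on mean nuclear mark
#' intensity with the hierarchical mixed model. Used for parameter-recovery
#' validation: the returned estimate should match `spec$genotype_effect`.
#'
#' @param spec A [synth_nuclei_spec()].
#' @param seed Integer seed.
#' @return One-row tibble: `effect_percent`, `p_value`, `n_nuclei`,
#'   `true_effect`.
#' @export
recover_intensity_effect <- function(spec, seed) {
  cohort <- gen_nuclei_cohort(spec, seed)
  q <- quantify_cohort(cohort)
  cmp <- compare_groups(q, "mean_mark_intensity",
                        reference = spec$genotypes[1])
  tibble::tibble(effect_percent = cmp$effect_percent,
                 p_value = cmp$p_value, n_nuclei = nrow(q),
                 true_effect = spec$genotype_effect)
}

#' Recover an injected punctum-volume effect
#'
#' Generates a puncta-bearing cohort, segments puncta in every nucleus and
#' compares mean punctum volume between genotypes as a percent excess of
#' the mutant over the control group.
#'
#' @param spec A [synth_nuclei_spec()] with a puncta component.
#' @param seed Integer seed.
#' @param min_volume Punctum volume filter, um^3.
#' @return One-row tibble: `effect_percent` (percent excess of mutant mean
#'   punctum volume), `n_puncta_control`, `n_puncta_mutant`, `true_effect`.
#' @export
recover_puncta_effect <- function(spec, seed, min_volume = 0.01) {
  cohort <- gen_nuclei_cohort(spec, seed)
  per_stack <- purrr::map(seq_along(cohort$stacks), function(i) {
    st <- cohort$stacks[[i]]
    masks <- suppressWarnings(
      segment_nuclei(st$dna, st$voxel_size))
    if (masks$n == 0) return(NULL)
    p <- segment_puncta(masks, st$mark, min_volume = min_volume)
    if (nrow(p) == 0) return(NULL)
    p$stack <- i
    p
  })
  per_stack <- purrr::compact(per_stack)
  if (length(per_stack) == 0)
    abort("no puncta recovered in any stack")
  puncta <- bind_rows(per_stack) |>
    left_join(cohort$samples, by = "stack")
  means <- puncta |>
    group_by(.data$genotype) |>
    summarise(mean_volume = mean(.data$volume), n = dplyr::n(),
              .groups = "drop")
  ctrl <- means$mean_volume[means$genotype == spec$genotypes[1]]
  mut <- means$mean_volume[means$genotype == spec$genotypes[2]]
  tibble::tibble(
    effect_percent = 100 * (mut / ctrl - 1),
    n_puncta_control = means$n[means$genotype == spec$genotypes[1]],
    n_puncta_mutant = means$n[means$genotype == spec$genotypes[2]],
    true_effect = spec$puncta$volume_effect %||% 0)
}
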