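#' Mixed-model comparison of per-nucleus measures between genotypes
#'
#' Fits a linear mixed model with genotype as the fixed effect and random
#' intercepts for larva and muscle-within-larva, the sampling hierarchy of
#' per-nucleus measurements. Positive measures are modelled on the natural
#' log scale by default, so the genotype effect back-transforms to a percent
#' change of the mutant group mean relative to control; an identity-scale
#' fit (effect as percent of the control mean) is used automatically when
#' the measure is not strictly positive. Optionally adds a log10(volume)
#' covariate, with or without a genotype interaction, for fits of intensity
#' against nuclear volume.
#'
#' If the full fit is singular, the model falls back to a larva-only random
#' intercept and the result is flagged.
#'
#' @param quants Tibble with one row per nucleus: the measure column, plus
#'   `genotype`, `larva_id`, `muscle_id` (and `volume` if the covariate is
#'   requested).
#' @param measure Name of the measure column (string), e.g.
#'   `"mean_mark_intensity"`.
#' @param reference Genotype level treated as control (default: first level
#'   or `"control"` when present).
#' @param log_volume_covariate Add log10(volume)?
#' @param volume_interaction Also add genotype x log10(volume)?
#' @param response `"auto"` (default), `"log"` or `"identity"`.
#' @return A list of class `group_comparison`: `effect_percent`, `p_value`,
#'   `model` (the `lmerModLmerTest` fit), `response`, `singular_fallback`,
#'   `reference`, `comparison` (the non-reference level).
#' @export
compare_groups <- function(quants, measure = "mean_mark_intensity",
                           reference = NULL,
                           log_volume_covariate = FALSE,
                           volume_interaction = FALSE,
                           response = c("auto", "log", "identity")) {
  response <- match.arg(response)
  need <- c(measure, "genotype", "larva_id", "muscle_id")
  missing <- setdiff(need, names(quants))
  if (length(missing))
    abort(paste("quants lacks columns:", paste(missing, collapse = ", ")))
  d <- quants
  d$genotype <- as.factor(d$genotype)
  if (nlevels(d$genotype) < 2) abort("need at least two genotypes")
  reference <- reference %||%
    (if ("control" %in% levels(d$genotype)) "control"
     else levels(d$genotype)[1])
  d$genotype <- stats::relevel(d$genotype, ref = reference)
  if (min(rowSums(table(d$genotype, d$larva_id) > 0)) < 2)
    abort("need at least two larvae per genotype")
  y <- d[[measure]]
  if (response == "auto") response <- if (all(y > 0)) "log" else "identity"
  d$.y <- if (response == "log") log(y) else y

  fix <- ".y ~ genotype"
  if (log_volume_covariate) {
    d$.logvol <- log10(d$volume)
    fix <- paste(fix, "+ .logvol")
    if (volume_interaction) fix <- paste(fix, "+ genotype:.logvol")
  }
  full <- paste(fix, "+ (1 | larva_id) + (1 | larva_id:muscle_id)")
  fit <- suppressWarnings(suppressMessages(
    lmerTest::lmer(stats::as.formula(full), data = d)))
  fallback <- lme4::isSingular(fit, tol = 1e-4)
  if (fallback) {
    fit <- suppressWarnings(suppressMessages(
      lmerTest::lmer(stats::as.formula(paste(fix, "+ (1 | larva_id)")),
                     data = d)))
  }
  co <- stats::coef(summary(fit))
  comparison <- levels(d$genotype)[2]
  term <- paste0("genotype", comparison)
  beta <- co[term, "Estimate"]
  p <- co[term, "Pr(>|t|)"]
  eff <- if (response == "log") {
    100 * (exp(beta) - 1)
  } else {
    ctrl_mean <- mean(y[d$genotype == reference])
    if (ctrl_mean == 0) NA_real_ else 100 * beta / ctrl_mean
  }
  structure(list(effect_percent = eff, p_value = p, model = fit,
                 response = response, singular_fallback = fallback,
                 reference = reference, comparison = comparison,
                 measure = measure),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$measure, ": ", x$comparison, " vs ",
      x$reference, " = ", sprintf("%+.1f%%", x$effect_percent),
      " (p = ", signif(x$p_value, 3), ")",
      if (x$singular_fallback) " [larva-only random effect]", "\n",
      sep = "")
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  co <- stats::coef(summary(x$model))
  tibble::tibble(term = rownames(co),
                 estimate = co[, "Estimate"],
                 std_error = co[, "Std. Error"],
                 df = co[, "df"],
                 statistic = co[, "t value"],
                 p_value = co[, "Pr(>|t|)"])
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(effect_percent = x$effect_percent, p_value = x$p_value,
                 response = x$response,
                 singular_fallback = x$singular_fallback,
                 nobs = stats::nobs(x$model),
                 aic = stats::AIC(x$model),
                 sigma = stats::sigma(x$model))
}

#' Plot a group comparison
#'
#' Per-nucleus values by genotype with larva-level means overlaid.
#'
#' @param object A `group_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.group_comparison <- function(object, ...) {
  d <- object$model@frame
  d$genotype <- d$genotype
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$.y)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(y = if (object$response == "log")
      paste0("log ", object$measure) else object$measure, x = NULL)
}
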