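#' Long count table for model-based comparison
#'
#' Stacks expert counts and the aggregated counts of the chosen methods
#' into one long table (one row per image and source) with the image-level
#' covariates, ready for a quasi-Poisson comparison of counting sources.
#'
#' @param aggregates Output of [count_images()].
#' @param gold Gold-standard table.
#' @param sources Count sources to stack; `"expert"` plus any of
#'   `"median"`, `"mode"`, `"hdbscan"`, `"dbscan"`.
#' @param present_only Restrict to expert-present images (the usual
#'   analysis set for counts).
#' @param round_median Round fractional medians half-up.
#' @return Data frame `image_id`, `phase`, `quality`,
#'   `abundance_category`, `source` (factor, `"expert"` first), `count`.
#' @export
build_long_table <- function(aggregates, gold,
                             sources = c("expert", "median", "mode",
                                         "hdbscan"),
                             present_only = TRUE, round_median = TRUE) {
  d <- merge(aggregates, gold, by = "image_id")
  if (present_only) d <- d[d$expert_present, , drop = FALSE]
  rows <- lapply(sources, function(s) {
    count <- if (s == "expert") d$expert_count else d[[paste0("count_", s)]]
    if (s == "median" && round_median) count <- round_half_up(count)
    data.frame(image_id = d$image_id, phase = d$phase,
               quality = d$quality,
               abundance_category = d$abundance_category,
               source = s, count = count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$source <- factor(out$source, levels = sources)
  rownames(out) <- NULL
  out
}

#' Quasi-Poisson comparison of counting sources
#'
#' Fits a log-link Poisson-family generalized linear model of the counts on
#' the counting source plus optional image covariates, with a free
#' dispersion parameter estimated from the Pearson statistic
#' (quasi-likelihood). The analysis-of-deviance table for the model terms
#' is recorded under both the chi-square and the F convention, since the
#' two scale the same dispersion-adjusted deviance differences.
#'
#' @param long_table Output of [build_long_table()].
#' @param covariates Optional extra model terms (`"phase"`, `"quality"`,
#'   `"abundance_category"`).
#' @return Object of class `"qp_fit"`: the `glm` fit, the Pearson
#'   dispersion, and both analysis-of-deviance tables.
#' @export
fit_quasipoisson <- function(long_table, covariates = NULL) {
  if (length(unique(long_table$source)) < 2) {
    stop("need at least two count sources", call. = FALSE)
  }
  if (any(long_table$count < 0)) stop("counts must be non-negative",
                                      call. = FALSE)
  terms <- c("source", covariates)
  f <- stats::as.formula(paste("count ~", paste(terms, collapse = " + ")))
  dat <- long_table
  dat$phase <- factor(dat$phase)
  fit <- stats::glm(f, family = stats::quasipoisson(), data = dat)
  if (!fit$converged) stop("IRLS did not converge", call. = FALSE)
  structure(list(
    fit = fit,
    formula = f,
    dispersion = summary(fit)$dispersion,
    anova_chisq = stats::anova(fit, test = "Chisq"),
    anova_F = stats::anova(fit, test = "F")),
    class = "qp_fit")
}

#' @export
print.qp_fit <- function(x, ...) {
  cat("Quasi-Poisson count comparison:",
      deparse(x$formula), "\n")
  cat(sprintf("  dispersion (Pearson chi-square / df): %.3f\n",
              x$dispersion))
  print(stats::coef(summary(x$fit)))
  cat("\nAnalysis of deviance (chi-square convention):\n")
  print(x$anova_chisq)
  invisible(x)
}

#' @export
coef.qp_fit <- function(object, ...) stats::coef(object$fit)

#' Multiplicity-adjusted pairwise contrasts of a model factor
#'
#' All pairwise differences of estimated marginal means on the link scale,
#' with standard errors from the quasi-likelihood fit and p-values adjusted
#' for the family of pairwise comparisons (Tukey-style multivariate-t by
#' default).
#'
#' @param fit A [fit_quasipoisson()] result.
#' @param factor Model factor to contrast (default the counting source).
#' @param adjust Multiplicity adjustment passed to emmeans.
#' @return Data frame `contrast`, `estimate`, `se`, `df`, `z_ratio`,
#'   `p_adjusted`, with the adjustment recorded as an attribute.
#' @export
pairwise_contrasts <- function(fit, factor = "source", adjust = "tukey") {
  stopifnot(inherits(fit, "qp_fit"))
  if (!(factor %in% all.vars(fit$formula)[-1])) {
    stop("factor '", factor, "' is not in the fitted model", call. = FALSE)
  }
  emm <- emmeans::emmeans(fit$fit, specs = factor)
  s <- summary(emmeans::contrast(emm, method = "pairwise"), adjust = adjust)
  out <- data.frame(contrast = as.character(s$contrast),
                    estimate = s$estimate, se = s$SE, df = s$df,
                    z_ratio = s$estimate / s$SE,
                    p_adjusted = s$p.value, stringsAsFactors = FALSE)
  attr(out, "adjust") <- adjust
  out
}

#' Nagelkerke pseudo-R-squared
#'
#' Normalized likelihood-ratio R-squared:
#' `[1 - exp((2/n)(ll0 - ll1))] / [1 - exp((2/n) ll0)]`.
#'
#' @param loglik_model Log-likelihood of the fitted model.
#' @param loglik_null Log-likelihood of the intercept-only model.
#' @param n Number of observations.
#' @return Value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  stopifnot(n >= 1)
  if (loglik_model < loglik_null - 1e-8) {
    stop("model log-likelihood is below the null log-likelihood",
         call. = FALSE)
  }
  denom <- 1 - exp(2 * loglik_null / n)
  if (abs(denom) < 1e-12) {
    stop("saturated null model: Nagelkerke denominator is 0", call. = FALSE)
  }
  (1 - exp(2 * (loglik_null - loglik_model) / n)) / denom
}

#' Rank counting methods by logistic fit to expert presence
#'
#' For each method, fits a logistic regression of expert presence on the
#' method's count over the gold-standard images and reports the Nagelkerke
#' pseudo-R-squared, ranking the methods by how well their counts carry
#' the expert presence signal. This response/covariate choice is one
#' defensible reading of an under-specified analysis; it is an
#' interpretation, not a reproduction.
#'
#' @inheritParams build_long_table
#' @param methods Counting methods to rank.
#' @return Data frame `method`, `r2_nagelkerke`, sorted decreasing.
#' @export
method_fit_ranking <- function(aggregates, gold,
                               methods = c("median", "mode", "hdbscan"),
                               round_median = TRUE) {
  d <- merge(aggregates, gold, by = "image_id")
  r2 <- vapply(methods, function(m) {
    count <- d[[paste0("count_", m)]]
    if (m == "median" && round_median) count <- round_half_up(count)
    dat <- data.frame(present = d$expert_present, count = count)
    # near-separation is the expected regime: a method whose counts almost
    # perfectly signal presence drives the likelihood toward saturation
    fit <- suppressWarnings(
      stats::glm(present ~ count, family = stats::binomial(), data = dat))
    null <- stats::glm(present ~ 1, family = stats::binomial(), data = dat)
    nagelkerke_r2(as.numeric(stats::logLik(fit)),
                  as.numeric(stats::logLik(null)), nrow(dat))
  }, numeric(1))
  out <- data.frame(method = methods, r2_nagelkerke = unname(r2),
                    stringsAsFactors = FALSE)
  out[order(-out$r2_nagelkerke), , drop = FALSE]
}
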