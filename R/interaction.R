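#' Quasi-likelihood F-test for parallelism of dose-response lines
#'
#' Fits the complete grouped binomial model with treatment-specific intercepts
#' and slopes on ln concentration, removes the tested terms, and compares the
#' deviance change to the heterogeneity of the complete model:
#' `F = (delta deviance / delta df) / dispersion`, with the dispersion the
#' Pearson chi-square of the complete model divided by its residual degrees of
#' freedom (quasi-likelihood scaling). Under `hypothesis = "equal slopes"` the
#' treatment-by-ln(dose) interaction terms are removed (common slope,
#' treatment-specific intercepts); under `"equal lines"` the treatment terms
#' are removed as well.
#'
#' The test is invariant to the order of the datasets and to rescaling all
#' concentrations by a common factor.
#'
#' @param datasets List of two or more [bioassay_dataset()] objects, each
#'   individually fittable.
#' @param hypothesis `"equal slopes"` (default) or `"equal lines"`.
#' @return Object of class `parallelism_test`: list with `treatments`, `F`,
#'   `df1`, `df2`, `p_value`, `hypothesis`, `dispersion`, `delta_deviance`.
#' @examples
#' fx <- bti_fixtures()$datasets
#' compare_slopes(fx[c("Cry10Aa", "Cyt2Ba")])
#' @export
compare_slopes <- function(datasets, hypothesis = c("equal slopes", "equal lines")) {
  hypothesis <- match.arg(hypothesis)
  if (!is.list(datasets) || length(datasets) < 2L)
    stop("need at least two datasets", call. = FALSE)
  for (d in datasets) {
    if (!inherits(d, "bioassay_dataset"))
      stop("datasets must be bioassay_dataset objects", call. = FALSE)
    ok <- tryCatch({ fit_logit(d); TRUE },
                   error = function(e) FALSE, warning = function(w) TRUE)
    if (!ok)
      stop(sprintf("dataset '%s' is not fittable", d$treatment_label),
           call. = FALSE)
  }
  stacked <- do.call(rbind, lapply(datasets, function(d) {
    g <- pool_replicates(d)$groups
    data.frame(trt = d$treatment_label, x = log(g$concentration),
               dead = g$n_dead, alive = g$n_total - g$n_dead,
               stringsAsFactors = FALSE)
  }))
  stacked$trt <- factor(stacked$trt)
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  full <- stats::glm(cbind(dead, alive) ~ trt * x, family = stats::binomial(),
                     data = stacked, control = ctl)
  reduced_formula <- if (hypothesis == "equal slopes")
    cbind(dead, alive) ~ trt + x else cbind(dead, alive) ~ x
  reduced <- stats::glm(reduced_formula, family = stats::binomial(),
                        data = stacked, control = ctl)
  df1 <- reduced$df.residual - full$df.residual
  df2 <- full$df.residual
  dispersion <- sum(stats::residuals(full, type = "pearson")^2) / df2
  ddev <- stats::deviance(reduced) - stats::deviance(full)
  Fval <- (ddev / df1) / dispersion
  structure(list(
    treatments = vapply(datasets, `[[`, "", "treatment_label"),
    F = Fval, df1 = df1, df2 = df2,
    p_value = stats::pf(Fval, df1, df2, lower.tail = FALSE),
    hypothesis = hypothesis, dispersion = dispersion,
    delta_deviance = ddev
  ), class = "parallelism_test")
}

#' @export
print.parallelism_test <- function(x, ...) {
  cat(sprintf("Parallelism test (%s): %s\n", x$hypothesis,
              paste(x$treatments, collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g  (dispersion %.3f)\n",
              x$df1, x$df2, x$F, x$p_value, x$dispersion))
  invisible(x)
}

#' Expected mixture LC50 under simple similar action
#'
#' Under the simple-similar-action null model the mixture components act as
#' dilutions of one another, and the expected LC50 of a binary mixture is the
#' proportion-weighted harmonic combination of the component LC50s:
#' `LC50(m) = 1 / (r_A / LC50(A) + r_B / LC50(B))`, where `r_A` and `r_B` are
#' the relative proportions (by mass concentration) of the two toxins in the
#' mixture. The result always lies between the two component LC50s.
#'
#' @param lc50_a,lc50_b Observed LC50s of the components, ng/mL (positive).
#' @param r_a,r_b Relative proportions, non-negative, summing to 1; defaults
#'   to an equal (1:1) mixture.
#' @return Expected mixture LC50, ng/mL.
#' @examples
#' expected_mixture_lc50(34.63, 279.37)   # 1:1 mixture
#' @export
expected_mixture_lc50 <- function(lc50_a, lc50_b, r_a = 0.5, r_b = 1 - r_a) {
  if (lc50_a <= 0 || lc50_b <= 0)
    stop("component LC50s must be positive", call. = FALSE)
  if (r_a < 0 || r_b < 0 || abs(r_a + r_b - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  1 / (r_a / lc50_a + r_b / lc50_b)
}

#' Synergism factor
#'
#' Ratio of the expected mixture LC50 under simple similar action to the
#' observed mixture LC50. Values above 1 indicate potentiation (synergy),
#' below 1 antagonism, and 1 additivity.
#'
#' @param lc50_expected Expected mixture LC50, ng/mL.
#' @param lc50_observed Observed (fitted) mixture LC50, ng/mL.
#' @return The synergism factor (dimensionless fold-change).
#' @examples
#' synergism_factor(61.62, 13.41)
#' @export
synergism_factor <- function(lc50_expected, lc50_observed) {
  if (lc50_expected <= 0 || lc50_observed <= 0)
    stop("LC50s must be positive", call. = FALSE)
  lc50_expected / lc50_observed
}

#' Relative potency of a treatment against a reference
#'
#' Potency is the ratio `LC50(reference) / LC50(treatment)`: values above 1
#' mean the treatment kills at lower concentrations than the reference. The
#' 95% limits treat the two fits as independent and combine the delta-method
#' variances of the two log-LC50s on the log-ratio scale (each covariance
#' inflated per the heterogeneity `policy`, as in [fieller_limits()]).
#'
#' @param fit_reference,fit_treatment [fit_logit()] fits.
#' @param confidence Confidence coefficient, default 0.95.
#' @param policy Heterogeneity policy, see [fieller_limits()].
#' @return Object of class `potency_estimate`: list with `treatment`,
#'   `reference`, `ratio`, `fl_lower`, `fl_upper`, `confidence`.
#' @examples
#' fx <- bti_fixtures()$datasets
#' relative_potency(fit_logit(fx[["Cyt2Ba"]]), fit_logit(fx[["Cry4Aa"]]))
#' @export
relative_potency <- function(fit_reference, fit_treatment, confidence = 0.95,
                             policy = c("floor", "always", "none")) {
  stopifnot(inherits(fit_reference, "dose_response_fit"),
            inherits(fit_treatment, "dose_response_fit"))
  policy <- match.arg(policy)
  lc_ref <- estimate_lc(fit_reference, 0.5)$value
  lc_trt <- estimate_lc(fit_treatment, 0.5)$value
  ratio <- lc_ref / lc_trt
  same <- identical(fit_reference, fit_treatment)
  if (same) {
    lims <- c(1, 1)
  } else {
    se <- sqrt(var_log_lc(fit_reference, 0.5, policy) +
                 var_log_lc(fit_treatment, 0.5, policy))
    q <- stats::qnorm(1 - (1 - confidence) / 2)
    lims <- exp(log(ratio) + c(-1, 1) * q * se)
  }
  structure(list(treatment = fit_treatment$treatment_label,
                 reference = fit_reference$treatment_label,
                 ratio = ratio, fl_lower = lims[1], fl_upper = lims[2],
                 confidence = confidence),
            class = "potency_estimate")
}

#' @export
print.potency_estimate <- function(x, ...) {
  cat(sprintf("Potency of %s vs %s: %.3f (%.0f%% limits %.3f - %.3f)\n",
              x$treatment, x$reference, x$ratio, 100 * x$confidence,
              x$fl_lower, x$fl_upper))
  invisible(x)
}

#' Flag a mixture as a synergy candidate from a single-concentration screen
#'
#' A cheap screen run before full concentration-mortality assays: the mixture
#' is flagged when its mortality exceeds the better of the two component
#' mortalities by more than `margin` percentage points. This is a heuristic
#' triage rule, not a formal test.
#'
#' @param component_a,component_b,mixture Single rows of a
#'   [screening_record()] (or lists with `treatment_label` and
#'   `mortality_mean`).
#' @param margin Percentage-point margin, default 20.
#' @return List with `flagged` (logical), `mixture_label`, `mixture_mortality`,
#'   `max_component_mortality` and `margin`.
#' @examples
#' fx <- bti_fixtures()$screen
#' screen_mixture(fx[1, ], fx[2, ], fx[3, ])
#' @export
screen_mixture <- function(component_a, component_b, mixture, margin = 20) {
  get1 <- function(r, what) {
    v <- r[[what]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("malformed screening record: missing ", what, call. = FALSE)
    v
  }
  ma <- get1(component_a, "mortality_mean")
  mb <- get1(component_b, "mortality_mean")
  mm <- get1(mixture, "mortality_mean")
  lab <- get1(mixture, "treatment_label")
  la <- get1(component_a, "treatment_label")
  lb <- get1(component_b, "treatment_label")
  if (!grepl(la, lab, fixed = TRUE) || !grepl(lb, lab, fixed = TRUE))
    stop(sprintf("mixture label '%s' does not name both components ('%s', '%s')",
                 lab, la, lb), call. = FALSE)
  best <- max(ma, mb)
  list(flagged = mm > best + margin,
       mixture_label = lab,
       mixture_mortality = mm,
       max_component_mortality = best,
       margin = margin)
}

#' Full synergism report for a set of treatments
#'
#' Orchestrates the whole pipeline over single-toxin and mixture datasets:
#' logit fit, LC50 with Fieller limits, expected mixture LC50 under simple
#' similar action, synergism factor, and relative potency against a reference
#' treatment. Mixtures are identified by their `components`: any dataset with
#' two components is paired with the single-toxin datasets named by them.
#' Each mixture row is annotated with the parallelism of its component lines
#' (simple similar action assumes parallel lines; when [compare_slopes()]
#' rejects at `alpha` the synergism factor is valid only at the LC50 point).
#'
#' @param datasets Named list of [bioassay_dataset()] objects, including the
#'   reference and, for every mixture, both of its components.
#' @param reference Treatment label used as the potency reference.
#' @param confidence Confidence coefficient for all limits.
#' @param policy Heterogeneity policy, see [fieller_limits()].
#' @param alpha Significance level for the parallel-lines annotation.
#' @return Data.frame of class `synergy_table` with one row per treatment:
#'   `treatment`, `slope`, `slope_se`, `intercept`, `intercept_se`,
#'   `dispersion`, `lc50`, `fl_lower`, `fl_upper`, `lc50_expected`,
#'   `synergism_factor`, `potency`, `potency_lower`, `potency_upper`,
#'   `parallel_components` (NA for single toxins).
#' @examples
#' tab <- synergy_table(bti_fixtures()$datasets)
#' tab[, c("treatment", "lc50", "synergism_factor", "potency")]
#' @export
synergy_table <- function(datasets, reference = "Cyt2Ba", confidence = 0.95,
                          policy = c("floor", "always", "none"), alpha = 0.05) {
  policy <- match.arg(policy)
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  labels <- vapply(datasets, `[[`, "", "treatment_label")
  names(datasets) <- labels
  if (!reference %in% labels && length(datasets) > 1L)
    stop(sprintf("reference treatment '%s' not among the datasets", reference),
         call. = FALSE)
  fits <- lapply(datasets, fit_logit)
  ref_fit <- if (reference %in% labels) fits[[reference]] else fits[[1L]]
  h <- function(f) sqrt(max(1, f$dispersion))

  rows <- lapply(labels, function(lab) {
    f <- fits[[lab]]
    lc <- fieller_limits(f, 0.5, confidence, policy)
    comp <- datasets[[lab]]$components
    expected <- sf <- NA_real_
    parallel <- NA
    if (length(comp) == 2L) {
      missing_comp <- setdiff(names(comp), labels)
      if (length(missing_comp))
        stop(sprintf("mixture '%s' lacks component dataset(s): %s",
                     lab, paste(missing_comp, collapse = ", ")), call. = FALSE)
      lc_a <- estimate_lc(fits[[names(comp)[1]]], 0.5)$value
      lc_b <- estimate_lc(fits[[names(comp)[2]]], 0.5)$value
      expected <- expected_mixture_lc50(lc_a, lc_b, comp[[1]], comp[[2]])
      sf <- synergism_factor(expected, lc$value)
      parallel <- compare_slopes(datasets[names(comp)])$p_value >= alpha
    }
    pot <- relative_potency(ref_fit, f, confidence, policy)
    data.frame(treatment = lab,
               slope = f$slope, slope_se = f$se_slope * h(f),
               intercept = f$intercept, intercept_se = f$se_intercept * h(f),
               dispersion = f$dispersion,
               lc50 = lc$value, fl_lower = lc$fl_lower, fl_upper = lc$fl_upper,
               lc50_expected = expected, synergism_factor = sf,
               potency = pot$ratio, potency_lower = pot$fl_lower,
               potency_upper = pot$fl_upper,
               parallel_components = parallel,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- ref_fit$treatment_label
  attr(out, "confidence") <- confidence
  attr(out, "policy") <- policy
  class(out) <- c("synergy_table", "data.frame")
  out
}

#' Write a synergy table as delimited text
#'
#' @param table A [synergy_table()].
#' @param path Output file path.
#' @param sep Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_synergy_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "synergy_table"))
  utils::write.table(as.data.frame(table), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
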