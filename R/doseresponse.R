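#' Fit a logit concentration-mortality regression
#'
#' Fits the quantal tolerance model `logit(p) = b0 + b1 * ln(concentration)`
#' to a treatment's grouped dead/total counts by binomial maximum likelihood
#' (iteratively reweighted least squares, convergence tolerance 1e-8, at most
#' 100 iterations). Replicate wells at the same concentration are pooled
#' before fitting; for a model with concentration as the only covariate this
#' leaves the likelihood, and hence the estimates, unchanged. Groups with 0%
#' or 100% mortality are retained in the likelihood; a 0.5-count continuity
#' correction is used only to build starting values from the empirical-logit
#' least-squares line.
#'
#' Heterogeneity beyond binomial sampling is quantified by the Pearson
#' dispersion (Pearson chi-square of the grouped fit divided by its residual
#' degrees of freedom); downstream interval estimates can inflate the
#' covariance by this factor (see [fieller_limits()]).
#'
#' @param dataset A [bioassay_dataset()] with at least two distinct
#'   concentrations and neither all-zero nor all-total deaths.
#' @param link `"logit"` (default) or `"probit"`.
#' @param abbott If `TRUE`, mortality is first corrected for natural (control)
#'   mortality by Abbott's formula. A no-op when control mortality is zero or
#'   unknown.
#' @return An object of class `dose_response_fit` with elements `slope`,
#'   `intercept`, `se_slope`, `se_intercept` (unscaled binomial SEs), `vcov`
#'   (unscaled), `dispersion`, `residual_deviance`, `df_residual`, `n_groups`,
#'   `loglik`, `separation` (logical flag for complete separation), `link`,
#'   `dose_transform` (`"natural log"`), `treatment_label`, `data` (the pooled
#'   groups used) and `glm` (the underlying fit).
#' @examples
#' fit <- fit_logit(bti_fixtures()$datasets[["Cyt2Ba"]])
#' coef(fit)
#' @export
fit_logit <- function(dataset, link = c("logit", "probit"), abbott = FALSE) {
  stopifnot(inherits(dataset, "bioassay_dataset"))
  link <- match.arg(link)
  pooled <- pool_replicates(dataset)
  g <- pooled$groups
  if (nrow(g) < 2L)
    stop("at least 2 distinct concentrations are required for fitting",
         call. = FALSE)
  if (sum(g$n_dead) == 0L || sum(g$n_dead) == sum(g$n_total))
    stop("all groups fully alive or fully dead: the tolerance model is not identifiable",
         call. = FALSE)

  x <- log(g$concentration)
  dead <- g$n_dead
  alive <- g$n_total - g$n_dead
  if (abbott) {
    ctl <- dataset$control
    c0 <- if (is.na(ctl$n_total) || ctl$n_total == 0L) 0 else ctl$n_dead / ctl$n_total
    if (c0 > 0) {
      p_adj <- pmax(0, (g$n_dead / g$n_total - c0) / (1 - c0))
      dead <- p_adj * g$n_total          # fractional counts allowed
      alive <- g$n_total - dead
    }
  }

  # empirical-logit least-squares start (0.5-count continuity correction for
  # the extreme groups; used for initialization only, never for the likelihood)
  p_corr <- (dead + 0.5) / (g$n_total + 1)
  z <- if (link == "logit") stats::qlogis(p_corr) else stats::qnorm(p_corr)
  start <- stats::coef(stats::lm(z ~ x))

  sep <- is_separated(x, dead, g$n_total)
  fit <- withCallingHandlers(
    stats::glm(cbind(dead, alive) ~ x,
               family = stats::binomial(link = link),
               start = start,
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|non-integer",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (sep)
    warning(sprintf("complete separation in '%s': estimates and limits are unreliable",
                    dataset$treatment_label), call. = FALSE)

  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  df_res <- fit$df.residual
  pearson <- sum(stats::residuals(fit, type = "pearson")^2)
  dispersion <- if (df_res > 0) pearson / df_res else NA_real_

  structure(list(
    slope = unname(b[2]), intercept = unname(b[1]),
    se_slope = sqrt(V[2, 2]), se_intercept = sqrt(V[1, 1]),
    vcov = unname(V),
    residual_deviance = stats::deviance(fit),
    df_residual = df_res,
    dispersion = dispersion,
    n_groups = nrow(g),
    loglik = as.numeric(stats::logLik(fit)),
    separation = sep,
    link = link,
    dose_transform = "natural log",
    treatment_label = dataset$treatment_label,
    data = g,
    glm = fit
  ), class = "dose_response_fit")
}

# complete separation: some dose kills everything above it and nothing below,
# with no partially-killed group in between
is_separated <- function(x, dead, total) {
  o <- order(x)
  p <- (dead / total)[o]
  all(p %in% c(0, 1)) && !is.unsorted(p)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("%s regression on ln(concentration): %s\n", x$link,
              x$treatment_label))
  h <- sqrt(max(1, x$dispersion))
  cat(sprintf("  slope     %8.4f +/- %.4f\n", x$slope, x$se_slope * h))
  cat(sprintf("  intercept %8.4f +/- %.4f\n", x$intercept, x$se_intercept * h))
  cat(sprintf("  %d groups, residual deviance %.3f on %d df, dispersion %.3f\n",
              x$n_groups, x$residual_deviance, x$df_residual, x$dispersion))
  if (x$separation) cat("  WARNING: complete separation; fit is unreliable\n")
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
vcov.dose_response_fit <- function(object, ...) object$vcov

#' Lethal-concentration point estimate
#'
#' Inverts the fitted tolerance curve at mortality `p`:
#' `LC_p = exp((link(p) - intercept) / slope)`, so for the logit link
#' `LC50 = exp(-intercept / slope)`.
#'
#' @param fit A [fit_logit()] fit.
#' @param p Target mortality proportion in (0, 1); default 0.5.
#' @return An object of class `lc_estimate` with elements `p`, `value`
#'   (ng/mL), `fl_lower`, `fl_upper` (NA until limits are attached, see
#'   [fieller_limits()]), `confidence` and `method`.
#' @examples
#' fit <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]])
#' estimate_lc(fit, 0.5)$value
#' @export
estimate_lc <- function(fit, p = 0.5) {
  stopifnot(inherits(fit, "dose_response_fit"), p > 0, p < 1)
  if (fit$slope == 0) stop("slope is zero: LC is undefined", call. = FALSE)
  if (fit$slope < 0)
    warning("negative slope: mortality decreases with concentration; LC value returned but suspect",
            call. = FALSE)
  zp <- link_quantile(p, fit$link)
  value <- exp((zp - fit$intercept) / fit$slope)
  structure(list(p = p, value = value, fl_lower = NA_real_, fl_upper = NA_real_,
                 confidence = NA_real_, method = NA_character_,
                 treatment_label = fit$treatment_label),
            class = "lc_estimate")
}

link_quantile <- function(p, link) {
  if (link == "logit") stats::qlogis(p) else stats::qnorm(p)
}

#' @export
print.lc_estimate <- function(x, ...) {
  cat(sprintf("LC%g for %s: %.4g ng/mL", 100 * x$p, x$treatment_label, x$value))
  if (!is.na(x$fl_lower))
    cat(sprintf("  (%.0f%% FL %.4g - %.4g, %s)", 100 * x$confidence,
                x$fl_lower, x$fl_upper, x$method))
  cat("\n")
  invisible(x)
}

#' Fieller fiducial limits for a lethal concentration
#'
#' Applies Fieller's theorem to the ratio `(link(p) - intercept) / slope` on
#' the ln-dose scale and exponentiates back to ng/mL. When the grouped fit is
#' heterogeneous (Pearson dispersion above 1) the covariance matrix is
#' inflated by the dispersion before the theorem is applied (`policy =
#' "floor"`, the default and classic quantal-assay practice); `"always"`
#' scales by the dispersion whatever its value, and `"none"` uses the pure
#' binomial covariance. When the Fieller g-statistic reaches 1 the interval is
#' unbounded and infinite limits are returned with a warning.
#'
#' @param fit A [fit_logit()] fit.
#' @param p Target mortality proportion in (0, 1).
#' @param confidence Confidence coefficient, default 0.95.
#' @param policy Heterogeneity policy: `"floor"`, `"always"` or `"none"`.
#' @return An `lc_estimate` whose `fl_lower`/`fl_upper` carry the limits.
#' @examples
#' fit <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]])
#' fieller_limits(fit, 0.5)
#' @export
fieller_limits <- function(fit, p = 0.5, confidence = 0.95,
                           policy = c("floor", "always", "none")) {
  stopifnot(inherits(fit, "dose_response_fit"),
            confidence > 0, confidence < 1)
  policy <- match.arg(policy)
  est <- estimate_lc(fit, p)
  V <- scaled_vcov(fit, policy)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12 * max(abs(ev))))
    stop("covariance matrix is not positive semi-definite", call. = FALSE)

  q <- stats::qnorm(1 - (1 - confidence) / 2)
  # ratio rho = N / D with N = link(p) - b0, D = b1, on the ln-dose scale
  N <- link_quantile(p, fit$link) - fit$intercept
  D <- fit$slope
  vNN <- V[1, 1]          # var(-b0) = var(b0)
  vND <- -V[1, 2]         # cov(link(p) - b0, b1)
  vDD <- V[2, 2]
  g <- q^2 * vDD / D^2
  if (g >= 1) {
    warning("Fieller g-statistic >= 1: fiducial limits are unbounded",
            call. = FALSE)
    lims <- c(0, Inf)
  } else {
    aa <- D^2 - q^2 * vDD
    bb <- -2 * (N * D - q^2 * vND)
    cc <- N^2 - q^2 * vNN
    disc <- bb^2 - 4 * aa * cc
    if (disc < 0) disc <- 0   # numerically degenerate (e.g. vanishing vcov)
    lims <- exp(sort((-bb + c(-1, 1) * sqrt(disc)) / (2 * aa)))
  }
  est$fl_lower <- lims[1]
  est$fl_upper <- lims[2]
  est$confidence <- confidence
  est$method <- "fieller"
  if (fit$separation)
    warning("limits computed from a separated fit are unreliable", call. = FALSE)
  est
}

scaled_vcov <- function(fit, policy) {
  h <- switch(policy,
              floor = max(1, fit$dispersion),
              always = fit$dispersion,
              none = 1)
  if (is.na(h)) h <- 1   # saturated two-point fit has no residual df
  fit$vcov * h
}

# delta-method variance of ln(LC_p); used for potency intervals
var_log_lc <- function(fit, p = 0.5, policy = "floor") {
  V <- scaled_vcov(fit, policy)
  m <- (link_quantile(p, fit$link) - fit$intercept) / fit$slope
  (V[1, 1] + 2 * m * V[1, 2] + m^2 * V[2, 2]) / fit$slope^2
}
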