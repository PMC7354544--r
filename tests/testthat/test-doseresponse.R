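test_that("a two-point design is fitted exactly through the empirical logits", {
  d <- bioassay_dataset("two", c(exp(1), exp(3)), c(100, 100), c(25, 75))
  f <- fit_logit(d)
  expect_equal(f$slope, log(3) / 1, tolerance = 1e-7)
  expect_equal(f$intercept, -2 * log(3), tolerance = 1e-7)
  expect_equal(f$residual_deviance, 0, tolerance = 1e-9)
  expect_equal(f$df_residual, 0L)
  # symmetric two-point design puts the LC50 at concentration 1
  d0 <- bioassay_dataset("sym", c(exp(-1), exp(1)), c(100, 100), c(25, 75))
  expect_equal(estimate_lc(fit_logit(d0), 0.5)$value, 1, tolerance = 1e-7)
})

test_that("ML fit agrees with an independent likelihood maximisation", {
  fx <- bti_fixtures()$datasets
  for (nm in names(fx)) {
    f <- fit_logit(fx[[nm]])
    o <- oracle_fit(f$data, start = c(f$intercept + 0.5, f$slope * 1.3))
    expect_equal(f$slope, o$slope, tolerance = 1e-4)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-4)
    expect_gte(f$loglik, o$loglik - 1e-6)
  }
  for (seed in c(3, 17, 29)) {
    d <- random_dataset(seed)
    f <- fit_logit(d)
    o <- oracle_fit(f$data, start = c(0, 1))
    expect_equal(binom_loglik(c(f$intercept, f$slope), log(f$data$concentration),
                              f$data$n_dead, f$data$n_total),
                 o$loglik, tolerance = 1e-6)
  }
})

test_that("fit structure satisfies its invariants", {
  f <- fit_logit(bti_fixtures()$datasets[["Cyt2Ba"]])
  expect_equal(f$vcov, t(f$vcov))
  expect_equal(f$se_slope, sqrt(f$vcov[2, 2]))
  expect_equal(f$se_intercept, sqrt(f$vcov[1, 1]))
  expect_equal(f$df_residual, f$n_groups - 2L)
  expect_identical(f$link, "logit")
  expect_identical(f$dose_transform, "natural log")
  expect_gt(f$dispersion, 0)
})

test_that("rescaling all concentrations rescales LC values and not the slope", {
  d <- bti_fixtures()$datasets[["Cry4Aa"]]
  k <- 7.3
  d2 <- bioassay_dataset(d$treatment_label, d$groups$concentration * k,
                         d$groups$n_total, d$groups$n_dead)
  f1 <- fit_logit(d); f2 <- fit_logit(d2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-6)
  for (p in c(0.1, 0.5, 0.9))
    expect_equal(estimate_lc(f2, p)$value, k * estimate_lc(f1, p)$value,
                 tolerance = 1e-6)
})

test_that("splitting groups into replicates leaves the fit unchanged", {
  d <- bti_fixtures()$datasets[["Cry10Aa"]]
  g <- d$groups
  split_conc <- rep(g$concentration, each = 2)
  split_dead <- as.vector(rbind(floor(g$n_dead / 2), ceiling(g$n_dead / 2)))
  split_total <- as.vector(rbind(floor(g$n_total / 2), ceiling(g$n_total / 2)))
  d2 <- bioassay_dataset("split", split_conc, split_total, split_dead,
                         replicate_id = rep(1:2, nrow(g)))
  f1 <- fit_logit(d); f2 <- fit_logit(d2)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-9)
  expect_equal(f2$intercept, f1$intercept, tolerance = 1e-9)
})

test_that("LC_p is monotone in p for a positive slope", {
  f <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]])
  ps <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  lcs <- vapply(ps, function(p) estimate_lc(f, p)$value, 0)
  expect_true(all(diff(lcs) > 0))
})

test_that("degenerate and pathological inputs are reported", {
  one_dose <- bioassay_dataset("one", c(5, 5), c(30, 40), c(10, 12),
                               replicate_id = 1:2)
  expect_error(fit_logit(one_dose), "at least 2 distinct")
  all_dead <- bioassay_dataset("dead", c(1, 10), c(30, 30), c(30, 30))
  expect_error(fit_logit(all_dead), "fully alive or fully dead")
  sep <- bioassay_dataset("sep", c(1, 10, 100, 1000), rep(30, 4),
                          c(0, 0, 30, 30))
  expect_warning(f <- fit_logit(sep), "complete separation")
  expect_true(f$separation)
  # declining mortality: LC returned with a warning
  dec <- bioassay_dataset("dec", c(1, 10, 100), c(50, 50, 50), c(40, 25, 10))
  f <- fit_logit(dec)
  expect_lt(f$slope, 0)
  expect_warning(estimate_lc(f, 0.5), "negative slope")
})

test_that("Fieller limits behave across uncertainty regimes", {
  f <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]])
  lc <- fieller_limits(f, 0.5)
  expect_lt(lc$fl_lower, lc$value)
  expect_gt(lc$fl_upper, lc$value)

  # vanishing covariance: both limits collapse onto the point estimate
  f0 <- f
  f0$vcov <- matrix(0, 2, 2)
  lc0 <- fieller_limits(f0, 0.5, policy = "none")
  expect_equal(lc0$fl_lower, lc0$value, tolerance = 1e-9)
  expect_equal(lc0$fl_upper, lc0$value, tolerance = 1e-9)

  # huge slope uncertainty: g >= 1 yields unbounded limits with a warning
  fbig <- f
  fbig$vcov <- matrix(c(0.01, 0, 0, 100), 2, 2)
  expect_warning(lcb <- fieller_limits(fbig, 0.5, policy = "none"),
                 "unbounded")
  expect_equal(unname(lcb$fl_upper), Inf)
})

test_that("Fieller limits agree with a parametric-bootstrap quantile oracle", {
  f <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]])
  lc <- fieller_limits(f, 0.5, policy = "none")
  set.seed(99)
  n <- 1e4
  V <- f$vcov
  L <- chol(V)
  draws <- matrix(stats::rnorm(2 * n), n, 2) %*% L
  b0 <- f$intercept + draws[, 1]
  b1 <- f$slope + draws[, 2]
  q <- stats::quantile(-b0 / b1, c(0.025, 0.975))
  expect_equal(log(lc$fl_lower), unname(q[1]), tolerance = 0.05)
  expect_equal(log(lc$fl_upper), unname(q[2]), tolerance = 0.05)
})

test_that("heterogeneity policies scale the interval width as documented", {
  f <- fit_logit(bti_fixtures()$datasets[["Cyt2Ba"]])   # dispersion > 1
  w <- function(lc) log(lc$fl_upper) - log(lc$fl_lower)
  expect_gt(w(fieller_limits(f, 0.5, policy = "floor")),
            w(fieller_limits(f, 0.5, policy = "none")))
  expect_equal(w(fieller_limits(f, 0.5, policy = "always")),
               w(fieller_limits(f, 0.5, policy = "floor")), tolerance = 1e-9)
  f2 <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]])  # dispersion < 1
  expect_equal(w(fieller_limits(f2, 0.5, policy = "floor")),
               w(fieller_limits(f2, 0.5, policy = "none")), tolerance = 1e-9)
  expect_lt(w(fieller_limits(f2, 0.5, policy = "always")),
            w(fieller_limits(f2, 0.5, policy = "none")))
})

test_that("Abbott correction is a no-op at zero control mortality and shifts the fit otherwise", {
  d <- bti_fixtures()$datasets[["Cry4Aa"]]
  f0 <- fit_logit(d)
  f1 <- fit_logit(d, abbott = TRUE)   # control deaths are zero
  expect_equal(f1$slope, f0$slope, tolerance = 1e-12)

  d2 <- bioassay_dataset(d$treatment_label, d$groups$concentration,
                         d$groups$n_total, d$groups$n_dead,
                         control = list(n_total = 100L, n_dead = 10L))
  f2 <- fit_logit(d2, abbott = TRUE)
  expect_gt(estimate_lc(f2, 0.5)$value, estimate_lc(f0, 0.5)$value)
})

test_that("probit link is available as an alternative dose-response model", {
  f <- fit_logit(bti_fixtures()$datasets[["Cry4Aa"]], link = "probit")
  expect_identical(f$link, "probit")
  expect_gt(f$slope, 0)
  lc <- estimate_lc(f, 0.5)$value
  expect_gt(lc, min(f$data$concentration))
  expect_lt(lc, max(f$data$concentration))
})
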