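# Independent oracles used across tests. These never call the package's
# fitting path: the log-likelihood is written out by hand and maximised with
# optim, so agreement with fit_logit is a genuine dual-route check.

binom_loglik <- function(theta, x, dead, total) {
  p <- stats::plogis(theta[1] + theta[2] * x)
  sum(stats::dbinom(dead, total, p, log = TRUE))
}

# Nelder-Mead maximiser of the grouped binomial logit likelihood
oracle_fit <- function(groups, start = c(0, 1)) {
  x <- log(groups$concentration)
  opt <- stats::optim(start, binom_loglik, x = x, dead = groups$n_dead,
                      total = groups$n_total,
                      control = list(fnscale = -1, maxit = 5000,
                                     reltol = 1e-14))
  list(intercept = opt$par[1], slope = opt$par[2], loglik = opt$value)
}

# small random grouped dataset with a monotone-toxic truth
random_dataset <- function(seed, n_doses = 5, label = "rand") {
  set.seed(seed)
  conc <- sort(exp(stats::runif(n_doses, 0, 6)))
  slope <- stats::runif(1, 0.4, 1.5)
  lc50 <- exp(stats::runif(1, 1, 5))
  total <- sample(30:80, n_doses, replace = TRUE)
  p <- stats::plogis(slope * (log(conc) - log(lc50)))
  dead <- stats::rbinom(n_doses, total, p)
  # keep the dataset fittable
  if (sum(dead) == 0) dead[n_doses] <- 1
  if (sum(dead) == sum(total)) dead[1] <- total[1] - 1
  bioassay_dataset(label, conc, total, dead)
}
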