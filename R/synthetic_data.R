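#' Specify a simulated concentration-mortality bioassay
#'
#' Describes the generating process for a single-treatment quantal bioassay
#' emulating replicate-well larvicide assays: wells of 10-15 larvae, a serial
#' dilution series of concentrations, binomial kill counts under a logit
#' tolerance model on natural-log concentration, zero control mortality, and
#' optional beta-binomial overdispersion across replicate wells.
#'
#' @param true_slope True logit slope per ln(ng/mL); must be positive.
#' @param true_lc50 True LC50, ng/mL; must be positive.
#' @param concentrations Tested concentrations, ng/mL; default the 3.3-fold
#'   serial dilution 2000, 666, 222, 74, 24.7, 8.2 used in the emulated
#'   assays.
#' @param larvae_range Integer range (min, max) of larvae per well; default
#'   10-15, drawn uniformly per well.
#' @param replicates Number of replicate wells per concentration; default 3.
#' @param rho Beta-binomial intra-well correlation in `[0, 1)`; 0 (default)
#'   gives pure binomial sampling.
#' @param treatment_label Label for the simulated treatment.
#' @param components Optional named proportions (for simulated mixtures).
#' @return Object of class `simulation_spec`.
#' @examples
#' sp <- simulation_spec(true_slope = 0.75, true_lc50 = 300)
#' simulate_bioassay(sp, seed = 1)
#' @export
simulation_spec <- function(true_slope, true_lc50,
                            concentrations = c(2000, 666, 222, 74, 24.7, 8.2),
                            larvae_range = c(10L, 15L),
                            replicates = 3L,
                            rho = 0,
                            treatment_label = "simulated",
                            components = NULL) {
  if (!is.numeric(true_slope) || true_slope <= 0)
    stop("true_slope must be positive", call. = FALSE)
  if (!is.numeric(true_lc50) || true_lc50 <= 0)
    stop("true_lc50 must be positive", call. = FALSE)
  if (any(concentrations <= 0) || anyDuplicated(concentrations))
    stop("concentrations must be positive and distinct", call. = FALSE)
  if (length(larvae_range) != 2L || larvae_range[1] > larvae_range[2] ||
      larvae_range[1] < 1L)
    stop("larvae_range must be a valid (min, max) pair", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  structure(list(true_slope = true_slope, true_lc50 = true_lc50,
                 concentrations = as.numeric(concentrations),
                 larvae_range = as.integer(larvae_range),
                 replicates = as.integer(replicates),
                 rho = rho, treatment_label = treatment_label,
                 components = components),
            class = "simulation_spec")
}

#' Simulate one bioassay dataset
#'
#' For every concentration and replicate, draws a well size uniformly from the
#' larvae range and a kill count from a binomial (or beta-binomial when
#' `rho > 0`) with mortality `plogis(true_slope * (ln c - ln LC50))`. Control
#' wells draw zero deaths, matching assays where mock-infected larvae never
#' die. Fully reproducible given `seed`.
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (so composite simulations can seed once at the top).
#' @return A [bioassay_dataset()] with replicate-level groups.
#' @export
simulate_bioassay <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  conc <- rep(spec$concentrations, each = spec$replicates)
  rep_id <- rep(seq_len(spec$replicates), times = length(spec$concentrations))
  n <- sample(seq(spec$larvae_range[1], spec$larvae_range[2]),
              length(conc), replace = TRUE)
  p <- stats::plogis(spec$true_slope * (log(conc) - log(spec$true_lc50)))
  dead <- draw_kills(n, p, spec$rho)
  n_control <- sum(sample(seq(spec$larvae_range[1], spec$larvae_range[2]),
                          spec$replicates, replace = TRUE))
  bioassay_dataset(spec$treatment_label, conc, n, dead, replicate_id = rep_id,
                   components = spec$components,
                   control = list(n_total = n_control, n_dead = 0L))
}

draw_kills <- function(n, p, rho) {
  if (rho == 0) return(stats::rbinom(length(n), n, p))
  shape <- 1 / rho - 1
  pi <- ifelse(p <= 0, 0,
               ifelse(p >= 1, 1,
                      stats::rbeta(length(p), p * shape, (1 - p) * shape)))
  stats::rbinom(length(n), n, pi)
}

#' Specify a simulated two-toxin mixture experiment
#'
#' Bundles two component specs with mixture proportions and a synergy
#' multiplier `s`: the mixture's true LC50 is the simple-similar-action
#' expected LC50 of the components divided by `s`, so `s = 1` simulates
#' additivity, `s > 1` potentiation and `s < 1` antagonism. The mixture's
#' slope defaults to the mean of the component slopes (the parallel-lines
#' assumption of the null model); its dilution series defaults to six
#' 3.3-fold steps centred on its true LC50.
#'
#' @param spec_a,spec_b Component [simulation_spec()]s.
#' @param r_a,r_b Mixture proportions, non-negative, summing to 1.
#' @param synergy Synergy multiplier `s > 0`; default 1 (additive).
#' @param mixture_slope True mixture slope; default `mean(slope_a, slope_b)`.
#' @param mixture_concentrations Mixture dilution series; default
#'   `lc50_mix * 3.3^(2.5, 1.5, 0.5, -0.5, -1.5, -2.5)`.
#' @return Object of class `mixture_simulation_spec`.
#' @examples
#' a <- simulation_spec(0.75, 300, treatment_label = "A")
#' b <- simulation_spec(0.60, 280, treatment_label = "B")
#' mspec <- mixture_simulation_spec(a, b, synergy = 1)
#' sim <- simulate_mixture_experiment(mspec, seed = 1)
#' names(sim)
#' @export
mixture_simulation_spec <- function(spec_a, spec_b, r_a = 0.5, r_b = 1 - r_a,
                                    synergy = 1, mixture_slope = NULL,
                                    mixture_concentrations = NULL) {
  stopifnot(inherits(spec_a, "simulation_spec"),
            inherits(spec_b, "simulation_spec"))
  if (r_a < 0 || r_b < 0 || abs(r_a + r_b - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  if (synergy <= 0) stop("synergy multiplier must be positive", call. = FALSE)
  expected <- expected_mixture_lc50(spec_a$true_lc50, spec_b$true_lc50, r_a, r_b)
  lc50_mix <- expected / synergy
  if (is.null(mixture_slope))
    mixture_slope <- mean(c(spec_a$true_slope, spec_b$true_slope))
  if (is.null(mixture_concentrations))
    mixture_concentrations <- lc50_mix * 3.3^seq(2.5, -2.5, by = -1)
  label <- paste(spec_a$treatment_label, spec_b$treatment_label, sep = "+")
  spec_m <- simulation_spec(
    true_slope = mixture_slope, true_lc50 = lc50_mix,
    concentrations = mixture_concentrations,
    larvae_range = spec_a$larvae_range, replicates = spec_a$replicates,
    rho = spec_a$rho, treatment_label = label,
    components = stats::setNames(c(r_a, r_b),
                                 c(spec_a$treatment_label,
                                   spec_b$treatment_label)))
  structure(list(spec_a = spec_a, spec_b = spec_b, spec_mixture = spec_m,
                 r_a = r_a, r_b = r_b, synergy = synergy,
                 expected_lc50 = expected),
            class = "mixture_simulation_spec")
}

#' Simulate a full two-toxin mixture experiment
#'
#' @param mspec A [mixture_simulation_spec()].
#' @param seed Optional integer seed for the whole experiment.
#' @return Named list of three [bioassay_dataset()]s: the two components and
#'   the mixture.
#' @export
simulate_mixture_experiment <- function(mspec, seed = NULL) {
  stopifnot(inherits(mspec, "mixture_simulation_spec"))
  if (!is.null(seed)) set.seed(seed)
  out <- list(simulate_bioassay(mspec$spec_a),
              simulate_bioassay(mspec$spec_b),
              simulate_bioassay(mspec$spec_mixture))
  names(out) <- vapply(out, `[[`, "", "treatment_label")
  out
}

#' Analyse one simulated mixture experiment
#'
#' Runs the estimation pipeline on a simulated experiment: fits all three
#' datasets, computes the observed mixture LC50, the expected LC50 from the
#' fitted component LC50s, and the synergism factor.
#'
#' @param experiment Output of [simulate_mixture_experiment()].
#' @param r_a,r_b Mixture proportions used in the analysis.
#' @return List with `lc50_a`, `lc50_b`, `lc50_mixture`, `lc50_expected`,
#'   `synergism_factor`.
#' @export
analyse_mixture_experiment <- function(experiment, r_a = 0.5, r_b = 1 - r_a) {
  stopifnot(is.list(experiment), length(experiment) == 3L)
  fits <- lapply(experiment, fit_logit)
  lc <- vapply(fits, function(f) estimate_lc(f, 0.5)$value, 0)
  expected <- expected_mixture_lc50(lc[1], lc[2], r_a, r_b)
  list(lc50_a = lc[[1]], lc50_b = lc[[2]], lc50_mixture = lc[[3]],
       lc50_expected = expected,
       synergism_factor = synergism_factor(expected, lc[[3]]))
}

#' Monte-Carlo recovery study
#'
#' Repeatedly simulates and re-analyses an experiment to quantify how well the
#' pipeline recovers the generating parameters. For a [simulation_spec()] it
#' reports bias, RMSE and fiducial-limit coverage for the slope and LC50; for
#' a [mixture_simulation_spec()] it additionally reports recovery of the
#' synergism factor (truth equal to the spec's synergy multiplier).
#'
#' @param spec A [simulation_spec()] or [mixture_simulation_spec()].
#' @param n_runs Number of simulated experiments (>= 2).
#' @param seed Integer seed for the whole study.
#' @param confidence Confidence coefficient for the coverage check.
#' @param policy Heterogeneity policy passed to [fieller_limits()].
#' @return A list with a `runs` data.frame (one row per simulation) and a
#'   `summary` list (bias, rmse, coverage, and for mixtures `mean_sf`,
#'   `sf_rmse`, `prop_sf_within_25pct`).
#' @examples
#' sp <- simulation_spec(0.75, 300, replicates = 3)
#' recovery_report(sp, n_runs = 5, seed = 1)$summary
#' @export
recovery_report <- function(spec, n_runs = 100L, seed = 1L, confidence = 0.95,
                            policy = "floor") {
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  set.seed(seed)
  if (inherits(spec, "simulation_spec")) {
    runs <- lapply(seq_len(n_runs), function(i) {
      d <- simulate_bioassay(spec)
      f <- suppressWarnings(fit_logit(d))
      lc <- suppressWarnings(fieller_limits(f, 0.5, confidence, policy))
      data.frame(run = i, slope = f$slope, lc50 = lc$value,
                 fl_lower = lc$fl_lower, fl_upper = lc$fl_upper,
                 covered = lc$fl_lower <= spec$true_lc50 &
                   spec$true_lc50 <= lc$fl_upper)
    })
    runs <- do.call(rbind, runs)
    summary <- list(
      true_slope = spec$true_slope, true_lc50 = spec$true_lc50,
      slope_bias = mean(runs$slope) - spec$true_slope,
      slope_rmse = sqrt(mean((runs$slope - spec$true_slope)^2)),
      lc50_bias = mean(runs$lc50) - spec$true_lc50,
      lc50_rmse = sqrt(mean((runs$lc50 - spec$true_lc50)^2)),
      fl_coverage = mean(runs$covered))
  } else if (inherits(spec, "mixture_simulation_spec")) {
    runs <- lapply(seq_len(n_runs), function(i) {
      ex <- simulate_mixture_experiment(spec)
      res <- suppressWarnings(analyse_mixture_experiment(ex, spec$r_a, spec$r_b))
      data.frame(run = i, lc50_mixture = res$lc50_mixture,
                 lc50_expected = res$lc50_expected,
                 synergism_factor = res$synergism_factor)
    })
    runs <- do.call(rbind, runs)
    sf <- runs$synergism_factor
    summary <- list(
      true_sf = spec$synergy,
      mean_sf = mean(sf),
      sf_rmse = sqrt(mean((sf - spec$synergy)^2)),
      prop_sf_within_25pct = mean(abs(sf / spec$synergy - 1) <= 0.25))
  } else {
    stop("spec must be a simulation_spec or mixture_simulation_spec",
         call. = FALSE)
  }
  list(runs = runs, summary = summary)
}
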