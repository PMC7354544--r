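#' Published Aedes aegypti bioassay fixtures
#'
#' The complete concentration-mortality counts of the published *A. aegypti*
#' second-instar bioassays of Bti delta-endotoxins: single-toxin series for
#' Cry10Aa, Cyt2Ba and Cry4Aa, and 1:1 (by mass concentration) mixture series
#' for Cry10Aa+Cyt2Ba and Cry4Aa+Cyt2Ba, together with the preliminary
#' single-concentration mixture screen and the reference logit coefficients of
#' the VectoBac-12AS wild-type positive control. Counts are the pooled
#' dead/total per concentration as published; control insects experienced no
#' mortality in any assay, so every control record stores zero deaths (control
#' group sizes were not published and are stored as `NA`).
#'
#' The Cyt2Ba series is common to both mixture experiments and appears once.
#'
#' @return A list with elements:
#' \describe{
#'   \item{datasets}{Named list of five [bioassay_dataset()] objects:
#'     `Cyt2Ba`, `Cry10Aa`, `Cry4Aa`, `Cry10Aa+Cyt2Ba`, `Cry4Aa+Cyt2Ba`.}
#'   \item{screen}{[screening_record()] data.frame of the 24 h
#'     single-concentration screen (four toxins, each alone, paired with
#'     Cyt2Ba, and as a 1:1 mixture).}
#'   \item{reference}{List with `vectobac = list(slope, intercept)`, the
#'     published logit regression coefficients (per ln ng/mL) of the
#'     VectoBac-12AS positive control, whose raw counts were not published.}
#' }
#' @examples
#' fx <- bti_fixtures()
#' fit <- fit_logit(fx$datasets[["Cyt2Ba"]])
#' estimate_lc(fit, 0.5)
#' @export
bti_fixtures <- function() {
  datasets <- list(
    "Cyt2Ba" = bioassay_dataset(
      "Cyt2Ba",
      concentration = c(4000, 1333, 444, 148, 49.4, 16.4),
      n_total = c(92, 85, 94, 78, 86, 84),
      n_dead  = c(84, 64, 39, 28, 22, 21)),
    "Cry10Aa" = bioassay_dataset(
      "Cry10Aa",
      concentration = c(2000, 666, 222, 74, 24.7, 8.2),
      n_total = c(50, 50, 41, 44, 46, 42),
      n_dead  = c(39, 30, 23, 12, 6, 1)),
    "Cry4Aa" = bioassay_dataset(
      "Cry4Aa",
      concentration = c(486, 162, 54, 18, 6, 2),
      n_total = c(70, 71, 70, 73, 64, 71),
      n_dead  = c(63, 53, 42, 27, 13, 7)),
    "Cry10Aa+Cyt2Ba" = bioassay_dataset(
      "Cry10Aa+Cyt2Ba",
      concentration = c(300, 60, 12, 2.4, 4.8e-1, 9.6e-2),
      n_total = c(124, 114, 135, 131, 116, 120),
      n_dead  = c(115, 86, 75, 53, 34, 23),
      components = c("Cry10Aa" = 0.5, "Cyt2Ba" = 0.5)),
    "Cry4Aa+Cyt2Ba" = bioassay_dataset(
      "Cry4Aa+Cyt2Ba",
      concentration = c(54, 27, 13.5, 6.74, 3.36, 1.68),
      n_total = c(163, 155, 200, 142, 102, 73),
      n_dead  = c(139, 111, 87, 58, 11, 5),
      components = c("Cry4Aa" = 0.5, "Cyt2Ba" = 0.5))
  )
  screen <- screening_record(
    treatment_label = c("Cry10Aa", "Cyt2Ba", "Cry10Aa+Cyt2Ba",
                        "Cry4Aa", "Cyt2Ba", "Cry4Aa+Cyt2Ba",
                        "Cry4Ba", "Cyt2Ba", "Cry4Ba+Cyt2Ba",
                        "Cry11Aa", "Cyt2Ba", "Cry11Aa+Cyt2Ba"),
    concentration = c(40, 40, 80, 10, 10, 20, 0.02, 0.02, 0.04, 1.5, 1.5, 3),
    mortality_mean = c(26, 31, 93, 31, 28, 100, 32, 10, 43, 40, 21, 46),
    mortality_sd = c(5, 8, 6, 10, 23, 0, 18, 9, 19, 16, 14, 21))
  list(datasets = datasets,
       screen = screen,
       reference = list(vectobac = list(slope = 1.51, intercept = 3.44)))
}
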