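#' Construct a bioassay dataset
#'
#' A `bioassay_dataset` holds one treatment's full concentration series from a
#' quantal bioassay: for each tested concentration (and optionally each
#' replicate well) the number of larvae exposed and the number dead at the
#' scoring time, plus the mixture composition of the inoculum and the control
#' (zero-dose) record. Controls are stored separately because log-dose is
#' undefined at concentration zero.
#'
#' @param treatment_label Single character string naming the treatment.
#' @param concentration Numeric vector of tested concentrations (ng/mL),
#'   strictly positive. Repeated values are treated as replicate wells.
#' @param n_total Integer vector, larvae exposed per group.
#' @param n_dead Integer vector, larvae dead per group; `0 <= n_dead <= n_total`.
#' @param replicate_id Optional vector of replicate identifiers, recycled
#'   against `concentration`.
#' @param components Named numeric vector of relative proportions of the
#'   toxins making up the inoculum; must be non-negative and sum to 1.
#'   Defaults to a single component named after `treatment_label` with
#'   proportion 1 (a single-toxin treatment).
#' @param control Optional list or data.frame with elements `n_total` and
#'   `n_dead` for the mock-infected control wells. `n_total` may be `NA` when
#'   only the control mortality (zero deaths) is known. Defaults to a control
#'   with zero deaths and unknown total.
#'
#' @return An object of class `bioassay_dataset`: a list with elements
#'   `treatment_label`, `components`, `groups` (data.frame with columns
#'   `concentration`, `n_total`, `n_dead`, `replicate_id`) and `control`.
#' @examples
#' d <- bioassay_dataset("toxinA", c(10, 100), c(30, 30), c(5, 25))
#' pooled_mortality(d$groups[d$groups$concentration == 100, ])
#' @export
bioassay_dataset <- function(treatment_label, concentration, n_total, n_dead,
                             replicate_id = NA,
                             components = NULL,
                             control = list(n_total = NA_integer_, n_dead = 0L)) {
  stopifnot(is.character(treatment_label), length(treatment_label) == 1L)
  k <- length(concentration)
  if (length(n_total) != k || length(n_dead) != k)
    stop("concentration, n_total and n_dead must have equal length", call. = FALSE)
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("treated concentrations must be positive (controls are stored separately)",
         call. = FALSE)
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  bad <- which(n_dead < 0 | n_dead > n_total)
  if (length(bad))
    stop(sprintf("n_dead outside [0, n_total] in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  if (is.null(components)) components <- stats::setNames(1, treatment_label)
  if (is.null(names(components)) || any(!nzchar(names(components))))
    stop("components must be a named vector of proportions", call. = FALSE)
  if (any(components < 0) || abs(sum(components) - 1) > 1e-9)
    stop("component proportions must be non-negative and sum to 1", call. = FALSE)
  control <- validate_control(control)
  groups <- data.frame(
    concentration = as.numeric(concentration),
    n_total = as.integer(n_total),
    n_dead = as.integer(n_dead),
    replicate_id = rep_len(replicate_id, k),
    stringsAsFactors = FALSE
  )
  structure(
    list(treatment_label = treatment_label, components = components,
         groups = groups, control = control),
    class = "bioassay_dataset"
  )
}

validate_control <- function(control) {
  if (is.null(control)) control <- list(n_total = NA_integer_, n_dead = 0L)
  n_total <- as.integer(control$n_total)
  n_dead <- as.integer(control$n_dead)
  if (length(n_total) != 1L || length(n_dead) != 1L)
    stop("control must carry scalar n_total and n_dead", call. = FALSE)
  if (is.na(n_dead) || n_dead < 0)
    stop("control n_dead must be a non-negative count", call. = FALSE)
  if (!is.na(n_total) && n_dead > n_total)
    stop("control n_dead exceeds control n_total", call. = FALSE)
  list(concentration = 0, n_total = n_total, n_dead = n_dead)
}

#' @export
print.bioassay_dataset <- function(x, ...) {
  mix <- if (length(x$components) > 1L)
    paste0(" [mixture: ",
           paste(sprintf("%s %.2g", names(x$components), x$components),
                 collapse = " + "), "]")
  else ""
  cat(sprintf("Bioassay dataset: %s%s\n", x$treatment_label, mix))
  cat(sprintf("  %d groups, %d distinct concentrations, %d larvae (%d dead)\n",
              nrow(x$groups), length(unique(x$groups$concentration)),
              sum(x$groups$n_total), sum(x$groups$n_dead)))
  ctl <- x$control
  cat(sprintf("  control: %s dead%s\n", ctl$n_dead,
              if (is.na(ctl$n_total)) "" else sprintf(" / %d", ctl$n_total)))
  invisible(x)
}

#' Pooled mortality of concentration groups
#'
#' Pools replicate wells tested at the same concentration into a single
#' mortality proportion, `sum(n_dead) / sum(n_total)`. Pooling conserves both
#' totals, so grouped binomial fits are unchanged by it.
#'
#' @param groups Data.frame with columns `concentration`, `n_total`, `n_dead`
#'   (e.g. a subset of a dataset's `groups`); all rows must share one
#'   concentration.
#' @return The pooled mortality proportion.
#' @examples
#' pooled_mortality(data.frame(concentration = 5, n_total = c(20, 30),
#'                             n_dead = c(10, 5)))
#' @export
pooled_mortality <- function(groups) {
  if (!is.data.frame(groups) || nrow(groups) == 0L)
    stop("groups must be a non-empty data.frame", call. = FALSE)
  if (length(unique(groups$concentration)) != 1L)
    stop("all groups must share the same concentration", call. = FALSE)
  sum(groups$n_dead) / sum(groups$n_total)
}

#' Pool replicate wells of a dataset by concentration
#'
#' @param dataset A [bioassay_dataset()].
#' @return The dataset with one row per distinct concentration and
#'   `replicate_id` dropped.
#' @export
pool_replicates <- function(dataset) {
  stopifnot(inherits(dataset, "bioassay_dataset"))
  g <- dataset$groups
  agg <- stats::aggregate(cbind(n_total, n_dead) ~ concentration, data = g, FUN = sum)
  agg <- agg[order(agg$concentration), ]
  bioassay_dataset(dataset$treatment_label, agg$concentration, agg$n_total,
                   agg$n_dead, components = dataset$components,
                   control = dataset$control)
}

#' Read bioassay datasets from a delimited text file
#'
#' Reads a CSV/TSV table of concentration-mortality counts and returns one
#' validated [bioassay_dataset()] per treatment. Column names are resolved via
#' `dialect`, so files using other headers can be read without renaming.
#'
#' @param path Path to an existing delimited text file.
#' @param dialect Named list mapping the required roles `treatment`,
#'   `concentration`, `n_total`, `n_dead` (and optionally `replicate`) to the
#'   column names used in the file.
#' @param sep Field separator, default `","`.
#' @param pool If `TRUE`, replicate rows sharing a treatment and concentration
#'   are pooled; otherwise they are kept as replicate groups.
#' @return Named list of `bioassay_dataset` objects (empty list, with a
#'   warning, for a file with no data rows).
#' @seealso [write_bioassay_table()] for the inverse operation.
#' @export
read_bioassay_table <- function(path,
                                dialect = list(treatment = "treatment",
                                               concentration = "concentration",
                                               n_total = "n_total",
                                               n_dead = "n_dead",
                                               replicate = "replicate"),
                                sep = ",", pool = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    warning(sprintf("no data rows in %s; returning an empty list", path))
    return(list())
  }
  for (role in c("treatment", "concentration", "n_total", "n_dead")) {
    col <- dialect[[role]]
    if (is.null(col) || !col %in% names(df))
      stop(sprintf("column for role '%s' (%s) not found in %s",
                   role, if (is.null(col)) "unmapped" else col, path),
           call. = FALSE)
  }
  rep_col <- dialect[["replicate"]]
  has_rep <- !is.null(rep_col) && rep_col %in% names(df)
  out <- list()
  for (trt in unique(df[[dialect$treatment]])) {
    rows <- df[df[[dialect$treatment]] == trt, , drop = FALSE]
    conc <- as.numeric(rows[[dialect$concentration]])
    if (anyNA(conc))
      stop(sprintf("unparseable concentration for treatment '%s'", trt),
           call. = FALSE)
    dead <- rows[[dialect$n_dead]]
    tot <- rows[[dialect$n_total]]
    bad <- which(dead > tot)
    if (length(bad))
      stop(sprintf("n_dead > n_total for treatment '%s' at concentration %s",
                   trt, conc[bad[1]]), call. = FALSE)
    if (any(conc <= 0))
      stop(sprintf("non-positive concentration in a treated row of '%s'", trt),
           call. = FALSE)
    d <- bioassay_dataset(as.character(trt), conc, tot, dead,
                          replicate_id = if (has_rep) rows[[rep_col]] else NA)
    if (pool) d <- pool_replicates(d)
    out[[as.character(trt)]] <- d
  }
  out
}

#' Write bioassay datasets to a delimited text file
#'
#' Writes datasets in the same layout [read_bioassay_table()] reads, so a
#' write/read round trip reproduces concentrations and counts exactly.
#'
#' @param datasets A `bioassay_dataset` or list of them.
#' @param path Output file path.
#' @param sep Field separator, default `","`.
#' @return `path`, invisibly.
#' @export
write_bioassay_table <- function(datasets, path, sep = ",") {
  if (inherits(datasets, "bioassay_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    cbind(treatment = d$treatment_label, d$groups, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  names(df)[names(df) == "replicate_id"] <- "replicate"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Screening records for single-concentration mixture screens
#'
#' @param treatment_label Character vector of treatment names.
#' @param concentration Concentrations tested (ng/mL).
#' @param mortality_mean Mean replicate mortality, percent.
#' @param mortality_sd Standard deviation across replicates, percent.
#' @return Data.frame of class `screening_record` with one row per treatment.
#' @export
screening_record <- function(treatment_label, concentration, mortality_mean,
                             mortality_sd) {
  if (any(mortality_mean < 0 | mortality_mean > 100))
    stop("mortality_mean must lie in [0, 100] percent", call. = FALSE)
  if (any(mortality_sd < 0))
    stop("mortality_sd must be non-negative", call. = FALSE)
  out <- data.frame(treatment_label = treatment_label,
                    concentration = concentration,
                    mortality_mean = mortality_mean,
                    mortality_sd = mortality_sd,
                    stringsAsFactors = FALSE)
  class(out) <- c("screening_record", "data.frame")
  out
}
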