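#' Calibrate a log-normal law to a printed median and quartiles
#'
#' Closed-form moment-free calibration from the summaries that cohort
#' tables report (`median [P25, P75]`): `mu = ln(median)` and
#' `sigma = (ln P75 - ln P25) / (2 * qnorm(0.75))` (qnorm(0.75) = 0.67449).
#' The fit reproduces the median exactly and the two quartiles exactly when
#' they are log-symmetric about the median; otherwise it splits the
#' difference in log space (see [sample_cohort()] for the quantile-exact
#' two-piece generalisation the generator uses).
#'
#' @param median,p25,p75 Positive values with `p25 < median < p75`.
#' @return Named numeric `c(mu, sigma)` of the fitted log-normal.
#' @examples
#' calibrate_lognormal(1, exp(-0.67449), exp(0.67449))  # mu 0, sigma 1
#' @export
calibrate_lognormal <- function(median, p25, p75) {
  if (!(is.finite(median) && is.finite(p25) && is.finite(p75)))
    stop("calibration inputs must be finite")
  if (p25 <= 0) stop("calibration inputs must be positive")
  if (!(p25 < median && median < p75))
    stop("calibration inputs must satisfy p25 < median < p75")
  c(mu = log(median), sigma = (log(p75) - log(p25)) / (2 * stats::qnorm(0.75)))
}

# Two-piece (split) quantile calibration: scale parameters for the lower
# and upper half so that P25, median and P75 are all matched exactly.
# Reduces to the single-sigma fit when the quartiles are symmetric about
# the median (on the chosen scale).
calibrate_split <- function(median, p25, p75, log_scale = TRUE) {
  if (!(p25 < median && median < p75))
    stop("calibration inputs must satisfy p25 < median < p75")
  if (log_scale) {
    if (p25 <= 0) stop("calibration inputs must be positive")
    m <- log(median)
    z <- stats::qnorm(0.75)
    list(m = m, s_lo = (m - log(p25)) / z, s_hi = (log(p75) - m) / z,
         log_scale = TRUE)
  } else {
    z <- stats::qnorm(0.75)
    list(m = median, s_lo = (median - p25) / z, s_hi = (p75 - median) / z,
         log_scale = FALSE)
  }
}

# Map standard-normal latent draws through a split calibration
q_split <- function(z, cal) {
  x <- cal$m + ifelse(z < 0, cal$s_lo, cal$s_hi) * z
  if (cal$log_scale) exp(x) else x
}

#' Build one variable entry of a cohort specification
#'
#' Convenience constructor validating that each group's summary triple is a
#' proper `c(median, p25, p75)` with `p25 < median < p75`.
#'
#' @param family One of `"lognormal"`, `"lognormal-integer"`, `"mmse"`
#'   (see [cohort_spec()]).
#' @param NC,MCI Numeric `c(median, p25, p75)` per group.
#' @return A list consumable by [cohort_spec()].
#' @export
spec_variable <- function(family, NC, MCI) {
  for (g in list(NC, MCI))
    if (!(length(g) == 3 && g[2] < g[1] && g[1] < g[3]))
      stop("each group needs c(median, p25, p75) with p25 < median < p75")
  list(family = family, NC = unname(NC), MCI = unname(MCI))
}

#' Define a marker-distribution specification for cohort synthesis
#'
#' Describes, per group (NC/MCI) and per variable, the marginal
#' distribution via its printed `median [P25, P75]`, plus the dependence
#' structure (a Gaussian-copula rank-correlation matrix) and the group
#' sizes.  Marginal families:
#' \describe{
#'   \item{`lognormal`}{positive continuous markers (distances, times,
#'     rates, ratios), two-piece quantile-matched in log space;}
#'   \item{`lognormal-integer`}{as above, rounded to whole numbers (age,
#'     years of education);}
#'   \item{`mmse`}{two-piece normal, rounded to integers and censored to
#'     the scale range [0, 30] (the censoring preserves the calibrated
#'     median and quartiles exactly, unlike renormalising truncation).}
#' }
#'
#' @param variables Named list; each element is `list(family =, NC =
#'   c(median, p25, p75), MCI = c(median, p25, p75))`.
#' @param group_sizes Named integer vector `c(NC =, MCI =)`.
#' @param copula_corr Optional correlation matrix (variables x variables,
#'   unit diagonal, symmetric positive semi-definite) for the Gaussian
#'   copula; `NULL` means independent marginals.  No between-marker
#'   correlations are reported in the calibration tables, so any nonzero
#'   choice is a modelling assumption and is carried in the spec
#'   explicitly.
#' @param sex_female Optional named numeric `c(NC =, MCI =)`: probability
#'   that a participant is female, per group.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(variables, group_sizes = c(NC = 46L, MCI = 46L),
                        copula_corr = NULL, sex_female = NULL) {
  stopifnot(is.list(variables), length(names(variables)) == length(variables))
  for (v in variables)
    stopifnot(v$family %in% c("lognormal", "lognormal-integer", "mmse"),
              length(v$NC) == 3, length(v$MCI) == 3)
  stopifnot(all(c("NC", "MCI") %in% names(group_sizes)),
            all(group_sizes >= 1))
  k <- length(variables)
  if (!is.null(copula_corr)) {
    copula_corr <- as.matrix(copula_corr)
    if (!all(dim(copula_corr) == k))
      stop("copula_corr must be ", k, " x ", k)
    if (max(abs(copula_corr - t(copula_corr))) > 1e-8 ||
        max(abs(diag(copula_corr) - 1)) > 1e-8)
      stop("copula_corr must be symmetric with unit diagonal")
    if (min(eigen(copula_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("copula_corr must be positive semi-definite")
  }
  structure(list(variables = variables, group_sizes = group_sizes,
                 copula_corr = copula_corr, sex_female = sex_female),
            class = "cohort_spec")
}

#' Sample a synthetic cohort from a calibrated specification
#'
#' Draws `n_NC + n_MCI` participants.  Within each group a latent
#' standard-normal vector per participant (correlated across variables via
#' the spec's Gaussian copula, independent if none) is pushed through each
#' variable's two-piece quantile transform, so every marginal reproduces
#' its printed median and quartiles exactly (up to integer rounding for
#' discrete families).  Demographics follow the same mechanism; sex is
#' Bernoulli with the spec's per-group female proportion.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed yields the identical table.
#' @param group_sizes Optional override of the spec's group sizes (e.g.
#'   larger groups for calibration checks).
#' @return A data frame of class `cohort_table` with columns
#'   `participant_id`, `group` (factor NC/MCI), optionally `sex`, and one
#'   column per spec variable.
#' @export
sample_cohort <- function(spec, seed = 1L, group_sizes = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  sizes <- if (is.null(group_sizes)) spec$group_sizes else group_sizes
  stopifnot(all(c("NC", "MCI") %in% names(sizes)))
  vars <- spec$variables
  k <- length(vars)
  out <- lapply(c("NC", "MCI"), function(g) {
    n <- as.integer(sizes[[g]])
    Z <- if (is.null(spec$copula_corr)) {
      matrix(stats::rnorm(n * k), n, k)
    } else {
      MASS::mvrnorm(n, mu = rep(0, k), Sigma = spec$copula_corr)
    }
    cols <- lapply(seq_len(k), function(j) {
      v <- vars[[j]]
      q <- v[[g]]
      if (v$family == "mmse") {
        cal <- calibrate_split(q[1], q[2], q[3], log_scale = FALSE)
        pmin(30, pmax(0, round(q_split(Z[, j], cal))))
      } else {
        cal <- calibrate_split(q[1], q[2], q[3], log_scale = TRUE)
        x <- q_split(Z[, j], cal)
        if (v$family == "lognormal-integer") round(x) else x
      }
    })
    names(cols) <- names(vars)
    df <- as.data.frame(cols)
    df$group <- g
    if (!is.null(spec$sex_female))
      df$sex <- ifelse(stats::rbinom(n, 1, spec$sex_female[[g]]) == 1,
                       "female", "male")
    df
  })
  tab <- do.call(rbind, out)
  tab <- cbind(participant_id = sprintf("p-%04d", seq_len(nrow(tab))), tab)
  tab$group <- factor(tab$group, levels = c("NC", "MCI"))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

tbl <- function(family, nc_med, nc_p25, nc_p75, mci_med, mci_p25, mci_p75)
  spec_variable(family, c(nc_med, nc_p25, nc_p75), c(mci_med, mci_p25, mci_p75))

#' Packaged calibration preset: full cohort
#'
#' The marker-distribution specification of the full 46 NC + 46 MCI study
#' cohort: per-group median and quartiles of the demographics, MMSE and
#' all eight SEP digital biomarkers, with the per-group female proportions
#' (29/46 NC, 31/46 MCI).  Marginals are independent by default (no
#' between-marker correlations are published).
#'
#' @param copula_corr Optional correlation matrix passed through to
#'   [cohort_spec()] (11 variables, in the order returned).
#' @return A `cohort_spec`.
#' @export
table4_cohort_spec <- function(copula_corr = NULL) {
  cohort_spec(
    variables = list(
      age             = tbl("lognormal-integer", 68.00, 60.75, 79.00,  70.00, 64.75, 80.00),
      education_years = tbl("lognormal-integer", 12.00, 9.00, 15.25,   12.00, 9.00, 14.25),
      mmse            = tbl("mmse",              29, 28.00, 29.25,     26.00, 24.00, 29.00),
      metr_total      = tbl("lognormal",         0.26, 0.21, 0.38,     0.31, 0.25, 0.50),
      med_total_px    = tbl("lognormal",         8676.08, 7406.04, 10324.11, 10963.08, 9156.78, 12672.55),
      met_first_s     = tbl("lognormal",         1.12, 0.78, 1.75,     1.08, 0.82, 1.96),
      mee_first       = tbl("lognormal",         1.04, 1.01, 1.06,     1.03, 1.01, 1.10),
      et_crossing_s   = tbl("lognormal",         25.32, 19.00, 33.52,  32.18, 22.83, 43.30),
      ed_crossing_px  = tbl("lognormal",         7292.46, 5331.37, 8750.32, 8606.23, 6675.84, 10861.47),
      et_above_s      = tbl("lognormal",         16.51, 12.99, 25.22,  18.27, 13.40, 29.00),
      ed_above_px     = tbl("lognormal",         4497.86, 3567.56, 6036.56, 4279.95, 3508.07, 5780.54)
    ),
    group_sizes = c(NC = 46L, MCI = 46L),
    copula_corr = copula_corr,
    sex_female = c(NC = 29 / 46, MCI = 31 / 46)
  )
}

#' Packaged calibration preset: basic-education subgroup
#'
#' As [table4_cohort_spec()], but calibrated to the 29 NC + 31 MCI
#' basic-education (>9 years) subgroup summaries, including its female
#' proportions (17/29 NC, 17/31 MCI).
#'
#' @param copula_corr Optional correlation matrix (11 variables).
#' @return A `cohort_spec`.
#' @export
table5_cohort_spec <- function(copula_corr = NULL) {
  cohort_spec(
    variables = list(
      age             = tbl("lognormal-integer", 68.00, 61.00, 83.00,  72.00, 64.00, 80.00),
      education_years = tbl("lognormal-integer", 12.00, 9.00, 16.00,   12.00, 6.00, 15.00),
      mmse            = tbl("mmse",              29, 28.00, 30.00,     27.00, 24.00, 29.00),
      metr_total      = tbl("lognormal",         0.24, 0.20, 0.28,     0.30, 0.26, 0.50),
      med_total_px    = tbl("lognormal",         8469.29, 7071.54, 9285.65, 10473.75, 9189.11, 12848.72),
      met_first_s     = tbl("lognormal",         0.95, 0.77, 1.56,     1.25, 0.85, 2.30),
      mee_first       = tbl("lognormal",         1.04, 1.01, 1.08,     1.03, 1.01, 1.09),
      et_crossing_s   = tbl("lognormal",         22.65, 18.37, 28.17,  30.40, 22.98, 43.30),
      ed_crossing_px  = tbl("lognormal",         6515.23, 5128.11, 8748.07, 8391.10, 6912.21, 11023.95),
      et_above_s      = tbl("lognormal",         14.03, 12.45, 17.53,  17.72, 12.75, 29.02),
      ed_above_px     = tbl("lognormal",         4040.34, 2928.82, 5167.38, 4260.67, 3579.10, 5640.59)
    ),
    group_sizes = c(NC = 29L, MCI = 31L),
    copula_corr = copula_corr,
    sex_female = c(NC = 17 / 29, MCI = 17 / 31)
  )
}

#' Read a cohort specification from JSON
#'
#' Accepts the JSON shape written by [write_cohort_spec()].
#'
#' @param path JSON file path.
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  vars <- lapply(raw$variables, function(v)
    spec_variable(v$family, as.numeric(v$NC), as.numeric(v$MCI)))
  gs <- unlist(raw$group_sizes)
  cc <- if (length(raw$copula_corr)) as.matrix(raw$copula_corr) else NULL
  sf <- if (length(raw$sex_female)) unlist(raw$sex_female) else NULL
  cohort_spec(vars, group_sizes = gs, copula_corr = cc, sex_female = sf)
}

#' Write a cohort specification to JSON
#'
#' @param spec A `cohort_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  out <- unclass(spec)
  out$group_sizes <- as.list(out$group_sizes)
  if (!is.null(out$sex_female)) out$sex_female <- as.list(out$sex_female)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
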