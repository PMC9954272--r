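#' Two-group Kruskal-Wallis H rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H statistic on two groups against a
#' chi-square reference with 1 degree of freedom — on two groups this is
#' the rank-sum (Mann-Whitney) comparison up to the chi-square reference,
#' which is how the cohort tables are compared.  Degenerate input where
#' every pooled value is identical returns `H = 0, p = 1`.
#'
#' @param x,y Numeric vectors, the two groups (NAs dropped).
#' @return List with `statistic` (H), `p_value`, `method`.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # H = 3.857, p ~ 0.0495
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = 0, p_value = 1, method = "Kruskal-Wallis H"))
  kt <- stats::kruskal.test(list(x, y))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       method = "Kruskal-Wallis H")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson chi-square without continuity correction, df = 1, as used for
#' the sex comparison between groups.  Yates' correction can be switched
#' on.  A table with a zero row or column marginal has no defined
#' statistic and is reported as `NA`.
#'
#' @param counts 2x2 matrix of nonnegative integer counts.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return List with `statistic`, `p_value`, `method`.
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == 2L)) stop("counts must be a 2x2 table")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                method = "Pearson chi-square (undefined: zero marginal)"))
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = if (correct) "Pearson chi-square (Yates)" else "Pearson chi-square")
}

#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all score thresholds and the area under
#' it by the trapezoidal rule, which (with ties collapsed to single curve
#' vertices) equals the midrank Mann-Whitney estimator: the probability
#' that a random positive-class score exceeds a random negative-class
#' score, counting ties one half.  Higher scores must indicate the
#' positive class; orientation of each marker is the caller's
#' responsibility (see [sep_analyze()] for the convention used in the
#' pipeline).
#'
#' @param scores Numeric scores.
#' @param labels Class labels, coerced to character.
#' @param positive Label of the positive class (default `"MCI"`).
#' @param marker Optional marker name carried into the result.
#' @return An object of class `roc_result`: list with `points` (data frame
#'   `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `marker`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(1, 3, 2, 4), c("NC", "NC", "MCI", "MCI"))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, positive = "MCI", marker = NULL) {
  labels <- as.character(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to build a ROC curve")
  r <- rank(scores)                      # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (as.numeric(n0) * n1)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last_of_tie <- c(diff(scores[ord]) != 0, TRUE)
  pts <- data.frame(fpr = c(0, fp[last_of_tie] / n0),
                    tpr = c(0, tp[last_of_tie] / n1))
  structure(list(points = pts, auc = auc, marker = marker,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result>%s AUC = %.3f (%d pos / %d neg, %d curve points)\n",
              if (is.null(x$marker)) "" else paste0(" ", x$marker),
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

# Ridge-penalised logistic regression by IRLS on standardised predictors.
# Used only to stabilise coefficients under (quasi-)separation; the small
# fixed penalty keeps the linear predictor finite without materially
# changing a well-posed fit.
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, "/"))
  p <- ncol(Xs)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(Xs, w * Xs) + pen, crossprod(Xs, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  b <- beta[-1] / scl
  c(beta[1] - sum(beta[-1] * ctr / scl), b)
}

fit_logistic <- function(df, y, vars, ridge_lambda = 1e-2) {
  sep_flag <- FALSE
  fml <- stats::as.formula(paste("..y ~", paste(vars, collapse = " + ")))
  dat <- df[, vars, drop = FALSE]
  dat$..y <- y
  fit <- withCallingHandlers(
    stats::glm(fml, data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  coefs <- stats::coef(fit)
  if (sep_flag || anyNA(coefs)) {
    coefs <- ridge_logistic(as.matrix(df[, vars, drop = FALSE]), y,
                            lambda = ridge_lambda)
    names(coefs) <- c("(Intercept)", vars)
    sep_flag <- TRUE
  }
  list(fit = fit, coefficients = coefs, separation = sep_flag)
}

#' Forward (step-up) logistic selection over candidate biomarkers
#'
#' Dimension reduction for the small-sample, eight-marker setting: starting
#' from the intercept-only logistic model of group membership, repeatedly
#' add the candidate whose likelihood-ratio entry p-value is smallest,
#' provided it is below the entry threshold; stop when no candidate
#' qualifies.  There is no removal step (pure step-up).  Complete cases
#' over all candidates are used.  If the final fit shows (quasi-)
#' separation, coefficients are re-estimated by a small-ridge IRLS and the
#' result is flagged.
#'
#' @param cohort A `cohort_table` (or data frame) with a `group` column
#'   (NC/MCI) and the candidate columns.
#' @param candidates Character vector of candidate column names; defaults
#'   to the eight SEP biomarkers present in the cohort.
#' @param entry_p Entry threshold for the likelihood-ratio p-value (0.05).
#' @param positive Group treated as the event (default `"MCI"`).
#' @return An object of class `selection_result`: list with `selected`
#'   (ordered names), `entry_p_values` (named, one per step),
#'   `coefficients` of the final model (NULL if nothing selected),
#'   `separation` flag, `entry_threshold`, `n_used`.
#' @export
stepup_select <- function(cohort, candidates = sep_biomarker_names(cohort),
                          entry_p = 0.05, positive = "MCI") {
  stopifnot(length(candidates) >= 1, "group" %in% names(cohort))
  cc <- stats::complete.cases(cohort[, candidates, drop = FALSE])
  df <- as.data.frame(cohort)[cc, , drop = FALSE]
  y <- as.integer(as.character(df$group) == positive)
  if (length(unique(y)) < 2L) stop("both groups must be present")
  selected <- character(0)
  steps <- numeric(0)
  dev_cur <- stats::glm(y ~ 1, family = stats::binomial())$deviance
  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    devs <- vapply(pool, function(v) {
      f <- suppressWarnings(
        stats::glm(stats::as.formula(
          paste("y ~", paste(c(selected, v), collapse = " + "))),
          data = df, family = stats::binomial()))
      f$deviance
    }, numeric(1))
    pvals <- stats::pchisq(pmax(dev_cur - devs, 0), df = 1, lower.tail = FALSE)
    best <- which.min(pvals)
    if (pvals[best] >= entry_p) break
    selected <- c(selected, pool[best])
    steps <- c(steps, pvals[best]); names(steps)[length(steps)] <- pool[best]
    dev_cur <- devs[best]
  }
  final <- if (length(selected)) fit_logistic(df, y, selected) else NULL
  structure(list(selected = selected, entry_p_values = steps,
                 coefficients = if (is.null(final)) NULL else final$coefficients,
                 separation = if (is.null(final)) FALSE else final$separation,
                 entry_threshold = entry_p, n_used = nrow(df)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> step-up logistic selection (entry p <",
      x$entry_threshold, ")\n")
  if (!length(x$selected)) cat("  nothing selected\n")
  else for (k in seq_along(x$selected))
    cat(sprintf("  %d. %-15s entry p = %.4g\n", k, x$selected[k],
                x$entry_p_values[k]))
  if (x$separation) cat("  note: separation detected; ridge-stabilised fit\n")
  invisible(x)
}

#' Combined score from the selected biomarkers
#'
#' Fits the logistic model of group on the selected markers and returns
#' the linear predictor per row — the "combination" score whose ROC curve
#' summarises the joint discriminative value.  With a single selected
#' marker the combination is a monotone map of that marker, so its AUC is
#' identical.
#'
#' @param cohort A `cohort_table` / data frame with `group` and the
#'   selected columns.
#' @param selected Character vector of marker names (>= 1).
#' @param positive Event group (default `"MCI"`).
#' @return List with `scores` (linear predictor, NA where a marker is
#'   missing), `coefficients`, `separation`.
#' @export
fit_combination <- function(cohort, selected, positive = "MCI") {
  stopifnot(length(selected) >= 1)
  df <- as.data.frame(cohort)
  cc <- stats::complete.cases(df[, selected, drop = FALSE])
  y <- as.integer(as.character(df$group[cc]) == positive)
  fl <- fit_logistic(df[cc, , drop = FALSE], y, selected)
  b <- fl$coefficients
  scores <- rep(NA_real_, nrow(df))
  scores[cc] <- b[1] +
    as.matrix(df[cc, selected, drop = FALSE]) %*% b[-1]
  list(scores = scores, coefficients = b, separation = fl$separation)
}

#' Restrict a cohort to the basic-education subgroup
#'
#' Keeps participants with strictly more than `years` years of education
#' (default 9, the compulsory-schooling cut-off that defines the
#' basic-education subgroup).
#'
#' @param cohort A `cohort_table` / data frame with `education_years`.
#' @param years Strict lower bound (default 9).
#' @return The filtered cohort (possibly empty), class preserved.
#' @export
filter_basic_education <- function(cohort, years = 9) {
  stopifnot("education_years" %in% names(cohort))
  cohort[!is.na(cohort$education_years) & cohort$education_years > years, ,
         drop = FALSE]
}

#' Canonical SEP biomarker column names present in a cohort
#'
#' @param cohort A data frame.
#' @return Character vector, subset of the eight biomarker columns.
#' @export
sep_biomarker_names <- function(cohort) {
  intersect(c("metr_total", "met_first_s", "et_crossing_s", "et_above_s",
              "med_total_px", "mee_first", "ed_crossing_px", "ed_above_px"),
            names(cohort))
}

fmt_mq <- function(v) {
  q <- stats::quantile(v[!is.na(v)], c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3])
}

#' Run the full screening analysis pipeline
#'
#' Reproduces the analysis layout of the screening study on any cohort
#' table: (1) a group-comparison table — median (P25, P75) per group and a
#' Kruskal-Wallis p-value for each continuous variable (demographics,
#' MMSE, all biomarkers present) plus a chi-square comparison of sex; (2)
#' forward step-up logistic selection over the eight biomarkers; (3) ROC
#' curves and AUCs for MMSE, each retained biomarker and the fitted
#' combination.  When `subgroup_education` is set, the identical pipeline
#' is rerun on the basic-education subset and attached as `$subgroup`.
#'
#' Marker orientation for ROC scoring: a biomarker whose MCI median
#' exceeds its NC median is scored as-is, otherwise negated; MMSE is
#' always negated — so a higher score means "more MCI-like" for every
#' curve.  No multiple-testing correction is applied; the report carries
#' the number of tests performed.
#'
#' @param cohort A `cohort_table` / data frame with `group` and marker
#'   columns (and optionally `age`, `sex`, `education_years`, `mmse`).
#' @param subgroup_education `NULL`/`FALSE` for no subgroup run, or a
#'   number: rerun on participants with `education_years >` that value
#'   (use `TRUE` for the default cut-off 9).
#' @param entry_p Entry threshold for step-up selection.
#' @return An object of class `screening_report`: list with `comparison`
#'   (data frame), `selection`, `rocs` (named list of `roc_result`),
#'   `aucs` (named numeric), `n_tests`, `group_sizes` and optionally
#'   `subgroup` (a nested `screening_report`).
#' @export
sep_analyze <- function(cohort, subgroup_education = NULL, entry_p = 0.05) {
  df <- as.data.frame(cohort)
  stopifnot("group" %in% names(df))
  g <- as.character(df$group)
  stopifnot(all(g %in% c("NC", "MCI")))
  if (!all(c("NC", "MCI") %in% g)) stop("both groups must be nonempty")
  markers <- sep_biomarker_names(df)
  cont_vars <- c(intersect(c("age", "education_years", "mmse"), names(df)),
                 markers)
  rows <- lapply(cont_vars, function(v) {
    x <- df[[v]][g == "NC"]; y <- df[[v]][g == "MCI"]
    ts <- rank_sum_test(x, y)
    data.frame(variable = v, nc = fmt_mq(x), mci = fmt_mq(y),
               test = ts$method, statistic = ts$statistic,
               p_value = ts$p_value)
  })
  if ("sex" %in% names(df)) {
    counts <- table(factor(g, c("NC", "MCI")),
                    factor(df$sex, c("female", "male")))
    cs <- chi_square_2x2(t(counts))
    rows <- c(rows, list(data.frame(
      variable = "sex",
      nc = sprintf("%d/%d", counts["NC", "female"], counts["NC", "male"]),
      mci = sprintf("%d/%d", counts["MCI", "female"], counts["MCI", "male"]),
      test = cs$method, statistic = cs$statistic, p_value = cs$p_value)))
  }
  comparison <- do.call(rbind, rows)

  sel <- stepup_select(df, candidates = markers, entry_p = entry_p)
  rocs <- list()
  if ("mmse" %in% names(df))
    rocs$mmse <- roc_auc(-df$mmse, g, marker = "mmse")
  for (m in sel$selected) {
    dir <- sign(stats::median(df[[m]][g == "MCI"], na.rm = TRUE) -
                stats::median(df[[m]][g == "NC"], na.rm = TRUE))
    if (dir == 0) dir <- 1
    rocs[[m]] <- roc_auc(dir * df[[m]], g, marker = m)
  }
  if (length(sel$selected)) {
    comb <- fit_combination(df, sel$selected)
    rocs$combination <- roc_auc(comb$scores, g, marker = "combination")
  }
  report <- structure(list(
    comparison = comparison, selection = sel, rocs = rocs,
    aucs = vapply(rocs, `[[`, numeric(1), "auc"),
    n_tests = nrow(comparison),
    group_sizes = c(NC = sum(g == "NC"), MCI = sum(g == "MCI"))
  ), class = "screening_report")

  if (!is.null(subgroup_education) && !isFALSE(subgroup_education)) {
    cut <- if (isTRUE(subgroup_education)) 9 else as.numeric(subgroup_education)
    sub <- filter_basic_education(df, cut)
    report$subgroup <- sep_analyze(sub, subgroup_education = NULL,
                                   entry_p = entry_p)
  }
  report
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("<screening_report> NC n=%d, MCI n=%d; %d comparisons (no multiplicity correction)\n",
              x$group_sizes["NC"], x$group_sizes["MCI"], x$n_tests))
  cmp <- x$comparison
  cmp$statistic <- round(cmp$statistic, 3)
  cmp$p_value <- signif(cmp$p_value, 3)
  print(cmp, row.names = FALSE)
  cat("Step-up selection:",
      if (length(x$selection$selected)) paste(x$selection$selected, collapse = " + ")
      else "(none)", "\n")
  cat("AUCs:\n")
  for (m in names(x$aucs)) cat(sprintf("  %-15s %.3f\n", m, x$aucs[[m]]))
  if (!is.null(x$subgroup)) {
    cat("---- basic-education subgroup ----\n")
    print(x$subgroup)
  }
  invisible(x)
}
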