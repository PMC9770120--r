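#' Fit a covariate-adjusted logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (convergence tolerance 1e-8, at most 100 iterations), with Wald z
#' tests and 95% confidence intervals per coefficient. The fit is
#' delegated to [stats::glm()]; this wrapper adds the rank and separation
#' diagnostics the association pipeline relies on.
#'
#' @param outcome Binary outcome: 0/1, logical, or a `cohort_table`
#'   `status` vector ("case" = 1).
#' @param predictors data.frame or matrix of predictors (covariates
#'   included); factors are expanded by the usual treatment contrasts.
#' @return A `logistic_fit`: list with `coef` (data.frame of term, beta,
#'   se, z, p, or, ci_lo, ci_hi), the underlying `glm` object, and
#'   `converged`.
#' @export
fit_logistic <- function(outcome, predictors = NULL) {
  y <- coerce_binary(outcome)
  df <- if (is.null(predictors)) data.frame(.y = y)
        else data.frame(.y = y, as.data.frame(predictors))
  mm <- stats::model.matrix(.y ~ ., df)
  if (qr(mm)$rank < ncol(mm))
    stop("design matrix is rank deficient (collinear predictors)")
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  if (!fit$converged)
    stop("logistic fit did not converge in 100 IRLS iterations")
  if (any(abs(fit$coefficients) > 15) &&
      all(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
    stop("perfect separation detected: a predictor splits cases and controls exactly")
  s <- summary(fit)$coefficients
  co <- data.frame(term = rownames(s), beta = s[, 1], se = s[, 2],
                   z = s[, 3], p = s[, 4],
                   or = exp(s[, 1]),
                   ci_lo = exp(s[, 1] - 1.959964 * s[, 2]),
                   ci_hi = exp(s[, 1] + 1.959964 * s[, 2]),
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coef = co, glm = fit, converged = fit$converged),
            class = "logistic_fit")
}

coerce_binary <- function(outcome) {
  if (is.character(outcome) || is.factor(outcome)) {
    outcome <- as.character(outcome)
    if (!all(outcome %in% c("case", "control")))
      stop("character outcome must be 'case'/'control'")
    return(as.integer(outcome == "case"))
  }
  y <- as.integer(outcome)
  if (!all(y %in% c(0L, 1L))) stop("outcome must be binary")
  y
}

#' Odds ratio per 1 SD of a standardized PRS
#'
#' Fits `status ~ z + covariates` and reports exp of the PRS coefficient
#' with its Wald 95% CI and p-value, plus the covariate-free
#' discrimination of the score (DeLong AUC and CI). This is the
#' headline association metric for a PRS in a case-control cohort.
#'
#' @param prs A standardized `prs_vector`.
#' @param cohort A `cohort_table`; rows matched to `prs` by `sample_id`.
#' @param covariates Character vector of cohort column names to adjust
#'   for (e.g. `c("age", "sex", "bmi", paste0("pc", 1:20))`); default none.
#' @return An `assoc_report`: list with `pgs_id`, `covariates`, `or_1sd`,
#'   `or_ci`, `beta`, `se`, `p`, `auc`, `auc_ci`, `n_cases`, `n_controls`.
#' @export
or_per_sd <- function(prs, cohort, covariates = character()) {
  m <- match(prs$sample_id, cohort$sample_id)
  if (anyNA(m)) stop("sample(s) in PRS missing from cohort table")
  if (all(is.na(prs$z))) stop("PRS must be standardized before or_per_sd")
  keep <- !is.na(prs$z)
  y <- cohort$status[m][keep]
  df <- data.frame(z = prs$z[keep])
  for (cv in covariates) {
    if (is.null(cohort[[cv]])) stop("covariate '", cv, "' not in cohort table")
    df[[cv]] <- cohort[[cv]][m][keep]
  }
  fit <- fit_logistic(y, df)
  row <- fit$coef[fit$coef$term == "z", ]
  roc <- auc_delong(df$z[y == "case"], df$z[y == "control"])
  structure(list(pgs_id = attr(prs, "pgs_id"), covariates = covariates,
                 or_1sd = row$or, or_ci = c(row$ci_lo, row$ci_hi),
                 beta = row$beta, se = row$se, p = row$p,
                 auc = roc$auc, auc_ci = roc$ci,
                 n_cases = sum(y == "case"), n_controls = sum(y == "control"),
                 fit = fit),
            class = "assoc_report")
}

#' @export
print.assoc_report <- function(x, ...) {
  cat(sprintf("%s: OR_1sd = %.3f [%.3f-%.3f], P = %.3g; AUC = %.3f [%.3f-%.3f] (%d cases / %d controls)\n",
              x$pgs_id, x$or_1sd, x$or_ci[1], x$or_ci[2], x$p,
              x$auc, x$auc_ci[1], x$auc_ci[2], x$n_cases, x$n_controls))
  if (length(x$covariates))
    cat("  adjusted for:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}
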