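#' Woolf odds ratio for a 2x2 table
#'
#' OR = (a*d)/(b*c) with the Woolf log-scale standard error
#' sqrt(1/a + 1/b + 1/c + 1/d). When any cell is zero the
#' Haldane-Anscombe correction (0.5 added to every cell) is applied and
#' flagged.
#'
#' @param a,b,c,d Cell counts: `a` = exposed cases, `b` = exposed
#'   controls, `c` = unexposed cases, `d` = unexposed controls.
#' @return List with `or`, `ci` (95%), `log_se`, `p` (Wald), `corrected`.
#' @export
or_2x2 <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  log_or <- log((a * d) / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(log_or),
       ci = exp(log_or + c(-1, 1) * 1.959964 * se),
       log_se = se,
       p = 2 * stats::pnorm(-abs(log_or / se)),
       corrected = corrected)
}

#' Decile risk stratification of a standardized PRS
#'
#' Bins samples into 10 equal-count groups of increasing PRS (ties broken
#' by stable input order so group sizes differ by at most one) and
#' reports the crude odds ratios contrasting the top decile with all
#' remaining samples (OR_vsAll) and with the bottom decile (OR_vsLowest),
#' each with Woolf 95% CIs. When `covariates` are supplied,
#' covariate-adjusted logistic versions of both contrasts are also
#' reported; the crude 2x2 estimates remain the headline values.
#'
#' @param prs A standardized `prs_vector`.
#' @param cohort A `cohort_table`.
#' @param covariates Optional character vector of cohort columns for the
#'   adjusted contrasts.
#' @param n_bins Number of quantile bins (default 10).
#' @return A `decile_report`: list with `decile` (per-sample assignment,
#'   1 = lowest), `counts` (per-decile case/control), `or_vs_all`,
#'   `or_vs_lowest` (each an [or_2x2()] result), and optionally
#'   `adjusted` (list with the logistic contrasts).
#' @export
decile_analysis <- function(prs, cohort, covariates = NULL, n_bins = 10) {
  m <- match(prs$sample_id, cohort$sample_id)
  if (anyNA(m)) stop("sample(s) in PRS missing from cohort table")
  z <- prs$z
  if (all(is.na(z))) stop("PRS must be standardized before decile_analysis")
  keep <- which(!is.na(z))
  n <- length(keep)
  if (n < 2 * n_bins) stop("too few samples for ", n_bins, " bins")
  ord <- keep[order(z[keep])]           # stable: ties keep input order
  sizes <- rep(n %/% n_bins, n_bins)
  extra <- n %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  decile <- rep(NA_integer_, nrow(prs))
  decile[ord] <- rep(seq_len(n_bins), times = sizes)

  status <- cohort$status[m]
  counts <- data.frame(decile = seq_len(n_bins),
                       cases = tabulate(decile[status == "case"], n_bins),
                       controls = tabulate(decile[status == "control"], n_bins))
  top <- n_bins
  a <- counts$cases[top]; b <- counts$controls[top]
  or_all <- or_2x2(a, b, sum(counts$cases[-top]), sum(counts$controls[-top]))
  or_low <- or_2x2(a, b, counts$cases[1], counts$controls[1])

  out <- list(decile = decile, counts = counts,
              or_vs_all = or_all, or_vs_lowest = or_low)
  if (!is.null(covariates)) {
    in_top <- as.integer(decile == top)
    adj <- function(sub) {
      df <- data.frame(expo = in_top[sub])
      for (cv in covariates) df[[cv]] <- cohort[[cv]][m][sub]
      fit <- fit_logistic(status[sub], df)
      fit$coef[fit$coef$term == "expo", ]
    }
    out$adjusted <- list(
      vs_all = adj(which(!is.na(decile))),
      vs_lowest = adj(which(decile %in% c(1L, top)))
    )
  }
  class(out) <- "decile_report"
  out
}

#' @export
print.decile_report <- function(x, ...) {
  cat(sprintf("decile_report: OR_vsAll = %.2f [%.2f-%.2f]%s; OR_vsLowest = %.2f [%.2f-%.2f]%s\n",
              x$or_vs_all$or, x$or_vs_all$ci[1], x$or_vs_all$ci[2],
              if (x$or_vs_all$corrected) " (Haldane-corrected)" else "",
              x$or_vs_lowest$or, x$or_vs_lowest$ci[1], x$or_vs_lowest$ci[2],
              if (x$or_vs_lowest$corrected) " (Haldane-corrected)" else ""))
  invisible(x)
}

#' Greedy age/sex matching of controls to cases
#'
#' Selects, for each case in input order, the `ratio` unused controls of
#' the same sex with the nearest age. Shortfalls (a sex stratum running
#' out of controls) are reported in the `n_shortfall` attribute, never
#' fatal.
#'
#' @param cohort A `cohort_table`.
#' @param ratio Controls per case (default 1).
#' @return A `cohort_table` containing all cases plus the matched
#'   controls, with attributes `n_shortfall` and `mean_age_diff`.
#' @export
match_controls <- function(cohort, ratio = 1) {
  cases <- which(cohort$status == "case")
  picked <- integer(0)
  age_diffs <- numeric(0)
  avail <- split(which(cohort$status == "control"), cohort$sex[cohort$status == "control"])
  shortfall <- 0L
  for (i in cases) {
    pool <- avail[[cohort$sex[i]]]
    take <- min(ratio, length(pool))
    shortfall <- shortfall + (ratio - take)
    if (take > 0) {
      sel <- pool[order(abs(cohort$age[pool] - cohort$age[i]))[seq_len(take)]]
      picked <- c(picked, sel)
      age_diffs <- c(age_diffs, abs(cohort$age[sel] - cohort$age[i]))
      avail[[cohort$sex[i]]] <- setdiff(pool, sel)
    }
  }
  out <- cohort[sort(c(cases, picked)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_shortfall") <- shortfall
  attr(out, "mean_age_diff") <- if (length(age_diffs)) mean(age_diffs) else NA_real_
  out
}
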