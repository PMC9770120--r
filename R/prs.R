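#' Score samples with a harmonized polygenic score
#'
#' Computes the raw PRS for each sample as the weighted sum of
#' effect-allele dosages over the matched variants,
#' \eqn{s_j = \sum_i w_i d_{ij}}. Missing dosages are handled by
#' `missing_policy`:
#' \describe{
#'   \item{`"impute_af"`}{(default) replace a missing dosage with twice the
#'     cohort effect-allele frequency of that variant (the mean oriented
#'     dosage over non-missing samples), standard PRS practice;}
#'   \item{`"zero"`}{treat missing as homozygous non-effect;}
#'   \item{`"strict"`}{error on any missing dosage.}
#' }
#' A sample missing at every matched variant receives an `NA` score
#' regardless of policy.
#'
#' @param geno A `genotype_matrix`.
#' @param scoring A `scoring_file` or a `prs_harmonized` object.
#' @param missing_policy One of `"impute_af"`, `"zero"`, `"strict"`.
#' @param drop_ambiguous Passed to [harmonize()] when `scoring` is a
#'   scoring file.
#' @return A `prs_vector`: data.frame with columns `sample_id`, `raw`, `z`
#'   (`NA` until [standardize_prs()]), attributes `pgs_id` and `scope`.
#' @export
score_samples <- function(geno, scoring,
                          missing_policy = c("impute_af", "zero", "strict"),
                          drop_ambiguous = FALSE) {
  missing_policy <- match.arg(missing_policy)
  h <- if (inherits(scoring, "prs_harmonized")) scoring
       else harmonize(scoring, geno, drop_ambiguous = drop_ambiguous)
  d <- geno$dosage[, h$variant_index, drop = FALSE]
  # orient to the effect allele
  flip <- h$orientation < 0
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  all_missing <- rowSums(!is.na(d)) == 0L
  if (anyNA(d)) {
    if (missing_policy == "strict")
      stop("missing dosages present under missing_policy = 'strict'")
    fill <- if (missing_policy == "zero") rep(0, ncol(d)) else {
      m <- colMeans(d, na.rm = TRUE)   # = 2 x effect-allele frequency
      m[is.nan(m)] <- 0
      m
    }
    na_idx <- which(is.na(d))
    d[na_idx] <- fill[((na_idx - 1L) %/% nrow(d)) + 1L]
  }
  raw <- as.numeric(d %*% h$weight)
  raw[all_missing] <- NA_real_
  prs_vector(geno$sample_ids, raw, pgs_id = h$pgs_id)
}

#' Construct a PRS vector
#' @param sample_id Sample identifiers.
#' @param raw Raw scores.
#' @param z Standardized scores (optional).
#' @param pgs_id Score label.
#' @param scope Standardization scope, `NA` until standardized.
#' @return A `prs_vector` data.frame.
#' @export
prs_vector <- function(sample_id, raw, z = NA_real_, pgs_id = "PRS",
                       scope = NA_character_) {
  stopifnot(length(sample_id) == length(raw))
  structure(data.frame(sample_id = as.character(sample_id), raw = raw, z = z,
                       stringsAsFactors = FALSE),
            pgs_id = pgs_id, scope = scope,
            class = c("prs_vector", "data.frame"))
}

#' Standardize a PRS overall or within ancestry strata
#'
#' z-scores the raw PRS, \eqn{z = (s - \bar s)/\mathrm{sd}(s)} with the
#' n-1 denominator, either over the whole cohort or separately within
#' each ancestry stratum. Within-ancestry standardization is how scores
#' are made comparable across ancestry groups before pooled association.
#'
#' @param prs A `prs_vector`.
#' @param cohort A `cohort_table` with an `ancestry` column (required for
#'   `scope = "per_ancestry"`), rows matched to `prs` by `sample_id`.
#' @param scope `"overall"` or `"per_ancestry"`.
#' @return The `prs_vector` with `z` filled in and `scope` set.
#' @export
standardize_prs <- function(prs, cohort = NULL,
                            scope = c("overall", "per_ancestry")) {
  scope <- match.arg(scope)
  strata <- if (scope == "overall") rep("all", nrow(prs)) else {
    if (is.null(cohort) || is.null(cohort$ancestry))
      stop("per-ancestry standardization needs a cohort table with ancestry")
    m <- match(prs$sample_id, cohort$sample_id)
    if (anyNA(m)) stop("sample(s) in PRS missing from cohort table")
    cohort$ancestry[m]
  }
  z <- rep(NA_real_, nrow(prs))
  for (s in unique(strata)) {
    i <- which(strata == s & !is.na(prs$raw))
    if (length(i) < 2) stop("stratum '", s, "' has fewer than 2 scored samples")
    sd_s <- stats::sd(prs$raw[i])
    if (!is.finite(sd_s) || sd_s == 0)
      stop("zero-variance PRS in stratum '", s, "'")
    z[i] <- (prs$raw[i] - mean(prs$raw[i])) / sd_s
  }
  prs$z <- z
  attr(prs, "scope") <- scope
  prs
}

#' Combine standardized PRSs into an ensemble score
#'
#' `method = "mean"` (default) averages the component z-scores per sample
#' and re-standardizes — the minimal construction that pools scores
#' carrying partly orthogonal signal. `method = "stacked"` learns a
#' logistic combination of the component z-scores by stratified k-fold
#' cross-validation: each sample's ensemble raw score is its out-of-fold
#' linear predictor, avoiding in-sample optimism, then re-standardized.
#'
#' @param components List of >= 2 standardized `prs_vector`s over the same
#'   samples in the same order (a single component is returned unchanged
#'   after re-standardization).
#' @param method `"mean"` or `"stacked"`.
#' @param cohort `cohort_table` (required for `"stacked"`: supplies case
#'   status; also used for re-standardization scope if `scope` is
#'   `"per_ancestry"`).
#' @param scope Re-standardization scope.
#' @param folds Number of cross-validation folds for stacking.
#' @param seed RNG seed for fold assignment.
#' @return A standardized `prs_vector` with `pgs_id = "EnsemblePRS"`.
#' @export
ensemble_prs <- function(components, method = c("mean", "stacked"),
                         cohort = NULL, scope = "overall",
                         folds = 5, seed = 42) {
  method <- match.arg(method)
  stopifnot(length(components) >= 1)
  ids <- components[[1]]$sample_id
  for (p in components) {
    if (!identical(p$sample_id, ids))
      stop("ensemble components must cover identical samples in identical order")
    if (all(is.na(p$z))) stop("ensemble components must be standardized first")
  }
  zmat <- vapply(components, function(p) p$z, numeric(length(ids)))
  if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = length(ids))
  if (method == "mean" || length(components) == 1L) {
    raw <- rowMeans(zmat)
  } else {
    if (is.null(cohort)) stop("stacked ensemble needs a cohort table for case status")
    m <- match(ids, cohort$sample_id)
    if (anyNA(m)) stop("sample(s) missing from cohort table")
    y <- as.integer(cohort$status[m] == "case")
    fold <- local_seed(seed, stratified_folds(y, folds))
    raw <- rep(NA_real_, length(y))
    for (k in seq_len(folds)) {
      tr <- fold != k
      fit <- stats::glm.fit(cbind(1, zmat[tr, , drop = FALSE]), y[tr],
                            family = stats::binomial())
      raw[!tr] <- as.numeric(cbind(1, zmat[!tr, , drop = FALSE]) %*% fit$coefficients)
    }
  }
  out <- prs_vector(ids, raw, pgs_id = "EnsemblePRS")
  standardize_prs(out, cohort = cohort, scope = scope)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (g in unique(y)) {
    i <- which(y == g)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  fold
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}
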