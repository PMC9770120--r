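# Enumerate the ordered haplotype pairs (h1, h2) compatible with one
# unphased multi-SNV genotype. Haplotypes are bit-encoded integers
# (site s contributes 2^(s-1) when carrying the alt allele). A missing
# genotype at a site expands over all four allele pairs (marginalized,
# not dropped).
compatible_pairs <- function(g) {
  k <- length(g)
  h1 <- 0L; h2 <- 0L
  for (s in seq_len(k)) {
    bit <- bitwShiftL(1L, s - 1L)
    opts <- if (is.na(g[s])) list(c(0L, 0L), c(bit, 0L), c(0L, bit), c(bit, bit))
            else switch(as.character(g[s]),
                        "0" = list(c(0L, 0L)),
                        "1" = list(c(bit, 0L), c(0L, bit)),
                        "2" = list(c(bit, bit)),
                        stop("dosage must be 0, 1, 2 or NA"))
    n_old <- length(h1); n_opt <- length(opts)
    add1 <- vapply(opts, `[`, integer(1), 1)
    add2 <- vapply(opts, `[`, integer(1), 2)
    h1 <- rep(h1, times = n_opt) + rep(add1, each = n_old)
    h2 <- rep(h2, times = n_opt) + rep(add2, each = n_old)
  }
  list(h1 = h1, h2 = h2)
}

hap_label <- function(code, variants) {
  k <- nrow(variants)
  vapply(code, function(h) {
    bits <- bitwAnd(bitwShiftR(h, seq_len(k) - 1L), 1L)
    paste(ifelse(bits == 1L, variants$alt, variants$ref), collapse = "")
  }, character(1))
}

hap_code <- function(label, variants) {
  k <- nrow(variants)
  alleles <- strsplit(toupper(label), "")[[1]]
  if (length(alleles) != k)
    stop("haplotype '", label, "' length != number of SNVs (", k, ")")
  code <- 0L
  for (s in seq_len(k)) {
    if (alleles[s] == variants$alt[s]) code <- code + bitwShiftL(1L, s - 1L)
    else if (alleles[s] != variants$ref[s])
      stop("allele '", alleles[s], "' at site ", s, " is neither ref (",
           variants$ref[s], ") nor alt (", variants$alt[s], ")")
  }
  code
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Estimates haplotype frequencies over k SNVs (k <= 10) by
#' expectation-maximization under within-group Hardy-Weinberg
#' equilibrium: the E-step weights each sample's compatible diplotypes
#' proportionally to the product of current haplotype frequencies, the
#' M-step re-estimates frequencies from the expected haplotype counts.
#' Initialization is uniform over haplotypes compatible with at least one
#' sample (lexicographic order fixes any ties), so runs are
#' deterministic. The log-likelihood is non-decreasing across iterations;
#' convergence is declared when the largest frequency change falls below
#' `tol`.
#'
#' @param geno A `genotype_matrix` restricted to the haplotype SNVs.
#' @param max_iter Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance on frequencies (default 1e-8).
#' @return A `haplotype_table`: data.frame with `haplotype` (allele
#'   string), `code` (bit encoding), `freq`, sorted by decreasing
#'   frequency; attributes `loglik`, `n_iter`, `converged`, `n_samples`.
#' @export
em_haplotype_freq <- function(geno, max_iter = 1000, tol = 1e-8) {
  k <- nrow(geno$variants)
  if (k > 10) stop("haplotype EM supports at most 10 SNVs (2^k space)")
  d <- geno$dosage
  if (any(colSums(!is.na(d)) == 0))
    stop("SNV with all genotypes missing: ",
         vk_id(geno$variants)[which(colSums(!is.na(d)) == 0)[1]])
  n <- nrow(d)
  pat_key <- apply(d, 1, function(g) paste(ifelse(is.na(g), ".", g), collapse = ""))
  tab <- table(pat_key)
  pats <- names(tab); cnt <- as.numeric(tab)
  pairs <- lapply(pats, function(p) {
    g <- suppressWarnings(as.integer(strsplit(p, "")[[1]]))
    compatible_pairs(g)
  })
  n_h <- bitwShiftL(1L, k)
  observed <- sort(unique(unlist(lapply(pairs, function(pr) c(pr$h1, pr$h2)))))
  freq <- numeric(n_h)
  freq[observed + 1L] <- 1 / length(observed)

  converged <- FALSE; iter <- 0L
  ll_trace <- numeric(0)   # log-likelihood at the start of each iteration
  for (iter in seq_len(max_iter)) {
    counts <- numeric(n_h)
    ll <- 0
    for (u in seq_along(pats)) {
      pr <- pairs[[u]]
      pw <- freq[pr$h1 + 1L] * freq[pr$h2 + 1L]
      tot <- sum(pw)
      if (tot <= 0) next
      w <- cnt[u] * pw / tot
      counts_u <- tapply(c(w, w), c(pr$h1, pr$h2), sum)
      counts[as.integer(names(counts_u)) + 1L] <-
        counts[as.integer(names(counts_u)) + 1L] + counts_u
      ll <- ll + cnt[u] * log(tot)
    }
    ll_trace <- c(ll_trace, ll)
    new_freq <- counts / (2 * n)
    delta <- max(abs(new_freq - freq))
    freq <- new_freq
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("haplotype EM did not converge in ", max_iter, " iterations")
  # final log-likelihood at the converged frequencies
  ll <- 0
  for (u in seq_along(pats)) {
    pr <- pairs[[u]]
    tot <- sum(freq[pr$h1 + 1L] * freq[pr$h2 + 1L])
    ll <- ll + cnt[u] * log(max(tot, .Machine$double.xmin))
  }
  keep <- which(freq > 0) - 1L
  out <- data.frame(haplotype = hap_label(keep, geno$variants),
                    code = keep, freq = freq[keep + 1L],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, loglik = ll, loglik_trace = ll_trace, n_iter = iter,
            converged = converged, n_samples = n,
            class = c("haplotype_table", "data.frame"))
}

# posterior expected count of haplotype `target` (bit code) per sample,
# given haplotype frequencies `freq` (length 2^k)
expected_hap_dosage <- function(geno, freq, target) {
  d <- geno$dosage
  apply(d, 1, function(g) {
    pr <- compatible_pairs(g)
    pw <- freq[pr$h1 + 1L] * freq[pr$h2 + 1L]
    tot <- sum(pw)
    if (tot <= 0) return(0)
    sum(pw * ((pr$h1 == target) + (pr$h2 == target))) / tot
  })
}

#' Case-control test for a target haplotype
#'
#' Runs [em_haplotype_freq()] separately in cases, controls and the
#' combined sample; then tests association by logistic regression of
#' case status on each sample's posterior expected count of the target
#' haplotype (computed under the combined-sample frequencies), optionally
#' covariate-adjusted. A score-type dosage test: exact phase is never
#' required.
#'
#' @param geno A `genotype_matrix` restricted to the haplotype SNVs.
#' @param cohort A `cohort_table`.
#' @param target Haplotype as an allele string (e.g. `"CCAAATT"`) over
#'   the SNVs in `geno` order.
#' @param covariates Optional cohort column names to adjust for.
#' @return List with `freq_cases`, `freq_controls`, `freq_all` (target
#'   haplotype frequency estimates), `or` (per expected haplotype copy),
#'   `ci`, `p`, `tables` (the three `haplotype_table`s).
#' @export
haplotype_cc_test <- function(geno, cohort, target, covariates = NULL) {
  m <- match(geno$sample_ids, cohort$sample_id)
  if (anyNA(m)) stop("sample(s) in genotypes missing from cohort table")
  code <- hap_code(target, geno$variants)
  case <- cohort$status[m] == "case"
  sub <- function(rows) genotype_matrix(geno$dosage[rows, , drop = FALSE],
                                        geno$sample_ids[rows], geno$variants)
  t_case <- em_haplotype_freq(sub(which(case)))
  t_ctrl <- em_haplotype_freq(sub(which(!case)))
  t_all <- em_haplotype_freq(geno)
  getf <- function(tab) { i <- match(code, tab$code); if (is.na(i)) 0 else tab$freq[i] }
  f_case <- getf(t_case); f_ctrl <- getf(t_ctrl); f_all <- getf(t_all)
  if (f_case == 0 && f_ctrl == 0)
    stop("target haplotype '", target, "' absent from both groups")
  n_h <- bitwShiftL(1L, nrow(geno$variants))
  freq <- numeric(n_h); freq[t_all$code + 1L] <- t_all$freq
  dose <- expected_hap_dosage(geno, freq, code)
  df <- data.frame(dose = dose)
  for (cv in covariates) df[[cv]] <- cohort[[cv]][m]
  fit <- fit_logistic(cohort$status[m], df)
  row <- fit$coef[fit$coef$term == "dose", ]
  list(freq_cases = f_case, freq_controls = f_ctrl, freq_all = f_all,
       or = row$or, ci = c(row$ci_lo, row$ci_hi), p = row$p,
       tables = list(cases = t_case, controls = t_ctrl, all = t_all))
}
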