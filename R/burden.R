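#' Case-control allele frequency ratio (CCR / pseudo-CCR)
#'
#' CCR = effect-allele frequency in cases / frequency in controls.
#' Frequencies are NOT minor-allele folded, so the direction of
#' enrichment is preserved. Two substitution rules apply:
#' a variant absent from controls (control MAF 0) gets the lowest
#' nonzero control MAF as denominator — a pseudo-CCR, flagged; a variant
#' absent from cases is ignored (NA with the `ignored` flag).
#'
#' @param maf_cases,maf_controls Effect-allele frequencies (vectors ok).
#' @param min_nonzero_control_maf Denominator substitute for zero control
#'   MAF; required (and > 0) when any control MAF is 0. In a sequenced
#'   cohort this is typically a control singleton, 1/(2 * n_controls).
#' @return data.frame with columns `ccr`, `pseudo`, `ignored`.
#' @export
ccr <- function(maf_cases, maf_controls, min_nonzero_control_maf = NULL) {
  stopifnot(length(maf_cases) == length(maf_controls))
  if (any(maf_cases < 0 | maf_cases > 1 | maf_controls < 0 | maf_controls > 1,
          na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]")
  pseudo <- !is.na(maf_controls) & maf_controls == 0
  ignored <- !is.na(maf_cases) & maf_cases == 0
  denom <- maf_controls
  if (any(pseudo & !ignored)) {
    if (is.null(min_nonzero_control_maf) || min_nonzero_control_maf <= 0)
      stop("zero control MAF present: a positive min_nonzero_control_maf is required")
    denom[pseudo] <- min_nonzero_control_maf
  }
  out <- data.frame(ccr = maf_cases / denom, pseudo = pseudo & !ignored,
                    ignored = ignored)
  out$ccr[ignored] <- NA_real_
  out$pseudo[ignored] <- FALSE
  out
}

#' Validate a variant annotation table
#'
#' @param tab data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `impact` (high/moderate/low), `clinvar` (P/LP, VUS, benign,
#'   none).
#' @return The validated annotation table.
#' @export
as_variant_annotation <- function(tab) {
  need <- c("chrom", "pos", "ref", "alt", "gene", "impact", "clinvar")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(tab$impact %in% c("high", "moderate", "low")))
    stop("impact must be high, moderate or low")
  if (!all(tab$clinvar %in% c("P/LP", "VUS", "benign", "none")))
    stop("clinvar must be P/LP, VUS, benign or none")
  structure(tab, class = c("variant_annotation", "data.frame"))
}

#' Read a variant annotation TSV (CHR, POS, REF, ALT, GENE, IMPACT, CLINVAR)
#' @param path Path to the TSV.
#' @return A `variant_annotation` data.frame.
#' @export
read_variant_annotation <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("CHR", "POS", "REF", "ALT", "GENE", "IMPACT", "CLINVAR")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  as_variant_annotation(data.frame(
    chrom = as.character(tab$CHR), pos = as.integer(tab$POS),
    ref = toupper(tab$REF), alt = toupper(tab$ALT),
    gene = tab$GENE, impact = tab$IMPACT, clinvar = tab$CLINVAR,
    stringsAsFactors = FALSE))
}

#' @export
write_variant_annotation <- function(annot, path) {
  tab <- data.frame(CHR = annot$chrom, POS = annot$pos, REF = annot$ref,
                    ALT = annot$alt, GENE = annot$gene,
                    IMPACT = annot$impact, CLINVAR = annot$clinvar)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# column indices of geno selected by the qualifying-variant filter:
# (impact in `impact` OR clinvar in `clinvar`) AND alt allele frequency
# over the whole cohort < maf_max AND gene match (if given)
select_variants <- function(geno, annot, gene = NULL,
                            impact = "high", clinvar = "P/LP",
                            maf_max = 0.01) {
  key_g <- vk_id(geno$variants)
  key_a <- paste(annot$chrom, annot$pos, annot$ref, annot$alt, sep = ":")
  m <- match(key_g, key_a)
  qual <- !is.na(m) &
    (annot$impact[m] %in% impact | annot$clinvar[m] %in% clinvar)
  if (!is.null(gene)) qual <- qual & annot$gene[m] %in% gene
  if (!is.null(maf_max)) {
    af <- colMeans(geno$dosage, na.rm = TRUE) / 2
    qual <- qual & !is.na(af) & af < maf_max
  }
  which(qual)
}

carrier_flags <- function(geno, idx) {
  if (!length(idx)) return(rep(FALSE, length(geno$sample_ids)))
  d <- geno$dosage[, idx, drop = FALSE]
  rowSums(d >= 1, na.rm = TRUE) > 0   # missing treated as non-carrier
}

#' Carrier odds ratio for qualifying variants in a gene
#'
#' A carrier is a sample with at least one alternate allele at any
#' qualifying variant of the gene (qualifying = impact or ClinVar class
#' in the filter, cohort alt-allele frequency below `maf_max`). The OR
#' contrasts carrier status between cases and controls via [or_2x2()].
#'
#' @param geno A `genotype_matrix`.
#' @param cohort A `cohort_table` (matched to `geno` by sample id).
#' @param annot A `variant_annotation`.
#' @param gene Gene symbol(s).
#' @param impact Qualifying impact classes (default `"high"`).
#' @param clinvar Qualifying ClinVar classes (default `"P/LP"`).
#' @param maf_max Cohort alt-allele frequency cutoff (default 0.01;
#'   `NULL` disables).
#' @return List with `table` (2x2 counts), `or`, `ci`, `p`, `corrected`,
#'   `n_variants`.
#' @export
carrier_or <- function(geno, cohort, annot, gene,
                       impact = "high", clinvar = "P/LP", maf_max = 0.01) {
  m <- match(geno$sample_ids, cohort$sample_id)
  if (anyNA(m)) stop("sample(s) in genotypes missing from cohort table")
  idx <- select_variants(geno, annot, gene, impact, clinvar, maf_max)
  carrier <- carrier_flags(geno, idx)
  case <- cohort$status[m] == "case"
  a <- sum(carrier & case); b <- sum(carrier & !case)
  c_ <- sum(!carrier & case); d <- sum(!carrier & !case)
  res <- or_2x2(a, b, c_, d)
  list(table = matrix(c(a, c_, b, d), 2, 2,
                      dimnames = list(c("carrier", "non-carrier"),
                                      c("case", "control"))),
       or = res$or, ci = res$ci, p = res$p, corrected = res$corrected,
       n_variants = length(idx))
}

#' Gene-level collapsing test (two-sided Fisher exact)
#'
#' Exact hypergeometric two-sided p-value on the carrier 2x2 table of
#' [carrier_or()], via [stats::fisher.test()].
#'
#' @inheritParams carrier_or
#' @return List with `p`, `table`, `or` (conditional MLE from the exact
#'   test), `n_variants`.
#' @export
collapse_test <- function(geno, cohort, annot, gene,
                          impact = "high", clinvar = "P/LP", maf_max = 0.01) {
  co <- carrier_or(geno, cohort, annot, gene, impact, clinvar, maf_max)
  ft <- stats::fisher.test(co$table)
  list(p = ft$p.value, table = co$table, or = unname(ft$estimate),
       n_variants = co$n_variants)
}

#' Per-variant and per-gene rare-variant burden report
#'
#' For each qualifying variant: case and control effect-allele
#' frequencies and CCR (pseudo-CCR substitution applied, denominator =
#' minimum nonzero control MAF over the analyzed variants). For each
#' gene: carrier counts and OR, the Fisher collapsing p, gene-level CCR
#' both as the ratio of summed allele counts (default headline) and as
#' the ratio of mean per-variant MAFs, and optionally the
#' variance-component score test p.
#'
#' @inheritParams carrier_or
#' @param genes Gene symbols to report (default: all genes with a
#'   qualifying variant).
#' @param vc Also run [vc_score_test()] per gene?
#' @param covariates Covariate columns for the variance-component null
#'   model.
#' @return A `burden_report`: list with `variants` and `genes` data.frames.
#' @export
gene_burden <- function(geno, cohort, annot, genes = NULL,
                        impact = "high", clinvar = "P/LP", maf_max = 0.01,
                        vc = FALSE, covariates = NULL) {
  m <- match(geno$sample_ids, cohort$sample_id)
  if (anyNA(m)) stop("sample(s) in genotypes missing from cohort table")
  case <- cohort$status[m] == "case"
  idx <- select_variants(geno, annot, NULL, impact, clinvar, maf_max)
  key_a <- paste(annot$chrom, annot$pos, annot$ref, annot$alt, sep = ":")
  gene_of <- annot$gene[match(vk_id(geno$variants)[idx], key_a)]
  if (is.null(genes)) genes <- sort(unique(gene_of))
  keep <- gene_of %in% genes
  idx <- idx[keep]; gene_of <- gene_of[keep]
  if (!length(idx)) stop("no qualifying variants for the requested genes")

  d <- geno$dosage[, idx, drop = FALSE]
  ac_case <- colSums(d * case, na.rm = TRUE)
  an_case <- colSums(!is.na(d) & case) * 2
  ac_ctrl <- colSums(d * !case, na.rm = TRUE)
  an_ctrl <- colSums(!is.na(d) & !case) * 2
  maf_case <- ac_case / pmax(1, an_case)
  maf_ctrl <- ac_ctrl / pmax(1, an_ctrl)
  nz <- maf_ctrl[maf_ctrl > 0]
  min_ctrl <- if (length(nz)) min(nz) else NULL
  cc <- ccr(maf_case, maf_ctrl, min_ctrl)
  variants <- data.frame(geno$variants[idx, ], gene = gene_of,
                         maf_cases = maf_case, maf_controls = maf_ctrl,
                         ccr = cc$ccr, pseudo = cc$pseudo, ignored = cc$ignored,
                         row.names = NULL)

  rows <- lapply(genes, function(g) {
    gi <- idx[gene_of == g]
    co <- carrier_or(geno, cohort, annot, g, impact, clinvar, maf_max)
    ct <- stats::fisher.test(co$table)$p.value
    sel <- gene_of == g
    sum_ac_ratio <- {
      fc <- sum(ac_case[sel]) / max(1, sum(an_case[sel]))
      f0 <- sum(ac_ctrl[sel]) / max(1, sum(an_ctrl[sel]))
      ccr(fc, f0, min_ctrl)$ccr
    }
    mean_maf_ratio <- ccr(mean(maf_case[sel]), mean(maf_ctrl[sel]), min_ctrl)$ccr
    out <- data.frame(gene = g, n_variants = length(gi),
                      carriers_cases = co$table["carrier", "case"],
                      carriers_controls = co$table["carrier", "control"],
                      carrier_or = co$or, ci_lo = co$ci[1], ci_hi = co$ci[2],
                      fisher_p = ct,
                      ccr_allele_count = sum_ac_ratio,
                      ccr_mean_maf = mean_maf_ratio,
                      stringsAsFactors = FALSE)
    if (vc) out$vc_p <- vc_score_test(geno, cohort, variants = gi,
                                      covariates = covariates)$p
    out
  })
  structure(list(variants = variants, genes = do.call(rbind, rows),
                 min_nonzero_control_maf = min_ctrl),
            class = "burden_report")
}

#' Variance-component score test for a variant set
#'
#' SKAT-style test: with null fitted probabilities \eqn{\hat\mu_0} from a
#' logistic model of status on the covariates (intercept-only when none),
#' the statistic is \eqn{Q = \sum_j w_j^2 (g_j'(y - \hat\mu_0))^2}. Its
#' null distribution, a weighted sum of 1-df chi-squares with weights the
#' eigenvalues of the projected kernel, is approximated by Liu et al.'s
#' moment-matched noncentral chi-square (flagged approximate; no exact
#' Davies inversion). With one variant this reduces exactly to the 1-df
#' score test.
#'
#' @param geno A `genotype_matrix`.
#' @param cohort A `cohort_table`.
#' @param variants Column indices of the variant set (default all).
#' @param weights Per-variant weights; default Beta(MAF; 1, 25) density,
#'   the usual up-weighting of rarer variants.
#' @param covariates Cohort column names for the null model.
#' @return List with `Q`, `p`, `df_approx`, `n_variants`,
#'   `method = "liu"`.
#' @export
vc_score_test <- function(geno, cohort, variants = NULL, weights = NULL,
                          covariates = NULL) {
  m <- match(geno$sample_ids, cohort$sample_id)
  if (anyNA(m)) stop("sample(s) in genotypes missing from cohort table")
  y <- as.integer(cohort$status[m] == "case")
  if (is.null(variants)) variants <- seq_len(ncol(geno$dosage))
  if (!length(variants)) stop("empty variant set")
  g <- geno$dosage[, variants, drop = FALSE]
  if (anyNA(g)) {  # mean-impute missing dosages for the score statistic
    mu <- colMeans(g, na.rm = TRUE)
    na_idx <- which(is.na(g))
    g[na_idx] <- mu[((na_idx - 1L) %/% nrow(g)) + 1L]
  }
  if (is.null(weights)) {
    maf <- colMeans(g) / 2
    weights <- stats::dbeta(pmin(pmax(maf, 1e-8), 1 - 1e-8), 1, 25)
  }
  df0 <- if (is.null(covariates)) NULL else {
    d <- data.frame(row.names = seq_along(y))
    for (cv in covariates) d[[cv]] <- cohort[[cv]][m]
    d
  }
  fit0 <- if (is.null(df0)) stats::glm(y ~ 1, family = stats::binomial())
          else stats::glm(y ~ ., data = cbind(data.frame(y = y), df0),
                          family = stats::binomial())
  mu0 <- fit0$fitted.values
  v <- mu0 * (1 - mu0)
  if (all(v < 1e-12)) stop("degenerate null model fit (no outcome variance)")
  x <- stats::model.matrix(fit0)
  s <- as.numeric(crossprod(g, y - mu0))
  q <- sum(weights^2 * s^2)
  # kernel K = W (G' P G) W with P = V - VX(X'VX)^{-1}X'V, V diagonal
  gv <- g * v
  gvx <- crossprod(gv, x)
  xvx <- crossprod(x * v, x)
  a_mat <- crossprod(g, gv) - gvx %*% solve(xvx, t(gvx))
  k_mat <- a_mat * tcrossprod(weights)
  lambda <- eigen(k_mat, symmetric = TRUE, only.values = TRUE)$values
  lambda <- lambda[lambda > 1e-10 * max(lambda, 1)]
  if (!length(lambda)) stop("degenerate kernel: no positive eigenvalues")
  liu <- liu_pvalue(q, lambda)
  list(Q = q, p = liu$p, df_approx = liu$df, n_variants = length(variants),
       method = "liu")
}

# Liu-Tang-Zhang moment-matched p-value for Q ~ sum(lambda_i chi2_1)
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2 * (l + 2 * delta))
  t_star <- (q - c1) / sqrt(2 * c2)
  p <- stats::pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta,
                     lower.tail = FALSE)
  list(p = p, df = l)
}
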