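test_that("CCR applies the pseudo and ignored substitution rules", {
  plain <- ccr(0.02, 0.01)
  expect_equal(plain$ccr, 2)
  expect_false(plain$pseudo)

  # variant seen twice in cases only, denominator = control singleton
  ps <- ccr(2 / (2 * 1014), 0, min_nonzero_control_maf = 1 / (2 * 6009))
  expect_true(ps$pseudo)
  expect_equal(ps$ccr, 11.85, tolerance = 0.005)

  ig <- ccr(0, 0.01)
  expect_true(ig$ignored)
  expect_true(is.na(ig$ccr))

  expect_error(ccr(0.01, 0), "min_nonzero_control_maf")
  expect_error(ccr(1.2, 0.5), "\\[0, 1\\]")

  # reciprocal identity when both frequencies are nonzero
  set.seed(70)
  a <- runif(20, 0.01, 0.5); b <- runif(20, 0.01, 0.5)
  expect_equal(ccr(a, b)$ccr * ccr(b, a)$ccr, rep(1, 20), tolerance = 1e-12)
})

test_that("per-variant CCR centers near 1 under a null simulation", {
  set.seed(71)
  n <- 1500
  g <- random_geno(n, 60, maf = runif(60, 0.05, 0.4), seed = 71)
  status <- sample(c("case", "control"), n, TRUE, prob = c(0.2, 0.8))
  case <- status == "case"
  maf_case <- colMeans(g$dosage[case, ]) / 2
  maf_ctrl <- colMeans(g$dosage[!case, ]) / 2
  cc <- ccr(maf_case, maf_ctrl)
  expect_equal(median(cc$ccr), 1, tolerance = 0.05)
})

test_that("carrier OR reproduces printed counts and an enumeration oracle", {
  res <- or_2x2(9, 9, 1005, 6000)
  expect_equal(signif(res$or, 3), 5.97)

  set.seed(72)
  n <- 300
  co <- mini_cohort(status = sample(c("case", "control"), n, TRUE), n = n)
  dos <- matrix(rbinom(n * 6, 1, 0.04), n, 6)
  dos[sample(length(dos), 20)] <- NA
  vk <- variant_keys(rep("19", 6), 1:6 * 100, rep("C", 6), rep("A", 6))
  g <- genotype_matrix(dos, co$sample_id, vk)
  annot <- as_variant_annotation(data.frame(
    chrom = vk$chrom, pos = vk$pos, ref = vk$ref, alt = vk$alt,
    gene = rep(c("G1", "G2"), each = 3),
    impact = c("high", "high", "moderate", "high", "low", "high"),
    clinvar = c("none", "P/LP", "none", "none", "P/LP", "none"),
    stringsAsFactors = FALSE))
  res2 <- carrier_or(g, co, annot, "G1", impact = "high", clinvar = "P/LP",
                     maf_max = NULL)
  # oracle: exhaustive per-sample enumeration over qualifying variants
  qual <- which(annot$gene == "G1" &
                  (annot$impact == "high" | annot$clinvar == "P/LP"))
  carrier <- vapply(seq_len(n), function(i) {
    any(!is.na(dos[i, qual]) & dos[i, qual] >= 1)
  }, logical(1))
  case <- co$status == "case"
  a <- sum(carrier & case); b <- sum(carrier & !case)
  expect_equal(res2$table["carrier", "case"], a)
  expect_equal(res2$table["carrier", "control"], b)
  expect_equal(res2$or,
               or_2x2(a, b, sum(!carrier & case), sum(!carrier & !case))$or)
  # identical carrier rates give OR 1
  even <- or_2x2(10, 20, 40, 80)
  expect_equal(even$or, 1)
})

test_that("carrier counts grow monotonically as the filter relaxes", {
  sim <- sim_cohort(sim_config(n_cases = 60, n_controls = 300, seed = 73,
                               n_common_variants = 20))
  g <- sim$rare$geno; annot <- sim$rare$annot; co <- sim$cohort
  strict <- carrier_or(g, co, annot, "LDLR", impact = "high",
                       clinvar = "P/LP", maf_max = 0.005)
  loose <- carrier_or(g, co, annot, "LDLR", impact = c("high", "moderate"),
                      clinvar = c("P/LP", "VUS"), maf_max = 0.05)
  expect_gte(loose$table["carrier", "case"], strict$table["carrier", "case"])
  expect_gte(loose$table["carrier", "control"],
             strict$table["carrier", "control"])
  expect_gte(loose$n_variants, strict$n_variants)
})

test_that("collapsing test equals the exact hypergeometric sum", {
  # oracle: two-sided Fisher p as the sum of hypergeometric point masses
  # no larger than the observed one
  fisher_oracle <- function(a, b, c_, d) {
    m <- a + b; n_ <- c_ + d; k <- a + c_
    xs <- max(0, k - n_):min(k, m)
    probs <- dhyper(xs, m, n_, k)
    sum(probs[probs <= dhyper(a, m, n_, k) * (1 + 1e-7)])
  }
  tab <- matrix(c(9, 1005, 9, 6000), 2, byrow = TRUE,
                dimnames = list(c("carrier", "non-carrier"),
                                c("case", "control")))
  p_ref <- fisher_oracle(9, 9, 1005, 6000)
  p_pkg <- fisher.test(matrix(c(9, 1005, 9, 6000), 2))$p.value
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
  expect_lt(p_pkg, 0.001)

  sim <- sim_cohort(sim_config(n_cases = 80, n_controls = 400, seed = 74,
                               n_common_variants = 20))
  ct <- collapse_test(sim$rare$geno, sim$cohort, sim$rare$annot, "LDLR",
                      impact = "high", clinvar = "P/LP")
  a <- ct$table["carrier", "case"]; b <- ct$table["carrier", "control"]
  c_ <- ct$table["non-carrier", "case"]; d <- ct$table["non-carrier", "control"]
  expect_equal(ct$p, fisher_oracle(a, b, c_, d), tolerance = 1e-9)
  # equal carrier rates: maximal p
  even <- fisher.test(matrix(c(5, 50, 10, 100), 2))$p.value
  expect_equal(even, 1)
})

test_that("variance-component test reduces to the 1-df score test for one variant", {
  set.seed(75)
  n <- 400
  co <- mini_cohort(status = sample(c("case", "control"), n, TRUE), n = n)
  g <- random_geno(n, 1, maf = 0.2, seed = 75)
  g$dosage <- matrix(g$dosage[, 1], ncol = 1,
                     dimnames = dimnames(g$dosage))
  res <- vc_score_test(g, co, weights = 1)
  y <- as.integer(co$status == "case")
  mu <- mean(y); v <- mu * (1 - mu)
  x <- g$dosage[, 1]
  s <- sum(x * (y - mu))
  lam <- v * sum((x - mean(x))^2)
  expect_equal(res$Q, s^2, tolerance = 1e-10)
  expect_equal(res$p, pchisq(s^2 / lam, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("variance-component p is within 2-fold of a permutation oracle", {
  set.seed(76)
  n <- 250; m <- 6
  maf <- runif(m, 0.05, 0.2)
  g <- random_geno(n, m, maf = maf, seed = 76)
  burden <- rowSums(g$dosage)
  y <- rbinom(n, 1, plogis(-1 + 0.35 * burden))
  co <- mini_cohort(status = ifelse(y == 1, "case", "control"), n = n)
  w <- rep(1, m)
  res <- vc_score_test(g, co, weights = w)
  q_perm <- replicate(4000, {
    yp <- sample(y)
    sum(w^2 * as.numeric(crossprod(g$dosage, yp - mean(yp)))^2)
  })
  p_perm <- (1 + sum(q_perm >= res$Q)) / 4001
  expect_lt(res$p, 0.2)   # planted signal is detectable
  expect_lt(abs(log(res$p / p_perm)), log(2) + 1e-9)
})

test_that("gene_burden reports per-variant pseudo-CCRs and per-gene tables", {
  sim <- sim_cohort(sim_config(n_cases = 145, n_controls = 860, seed = 77,
                               n_common_variants = 20))
  rep_ <- gene_burden(sim$rare$geno, sim$cohort, sim$rare$annot,
                      impact = c("high", "moderate"))
  expect_setequal(unique(rep_$genes$gene),
                  unique(sim$rare$annot$gene))
  expect_true(all(rep_$variants$ccr[!rep_$variants$ignored] > 0, na.rm = TRUE))
  # planted control singleton defines the minimum nonzero control MAF
  n_ctrl <- sum(sim$cohort$status == "control")
  expect_lte(rep_$min_nonzero_control_maf, 1 / n_ctrl)
  expect_true(any(rep_$variants$pseudo | rep_$variants$ignored) ||
                all(rep_$variants$maf_controls > 0))
  # carrier counts bounded by group sizes
  expect_true(all(rep_$genes$carriers_cases <= sum(sim$cohort$status == "case")))
  expect_true(all(rep_$genes$carriers_controls <= n_ctrl))
})
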