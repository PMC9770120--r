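test_that("genomic lambda follows its definition and scales linearly", {
  expect_equal(genomic_lambda(rep(0.5, 11)), 1.0, tolerance = 1e-12)
  expect_error(genomic_lambda(numeric(0)), "empty")
  expect_error(genomic_lambda(c(0.5, 0)), "in \\(0, 1\\]")
  set.seed(61)
  p <- runif(10000)
  expect_gt(genomic_lambda(p), 0.95)
  expect_lt(genomic_lambda(p), 1.05)
  # doubling every chi-square doubles lambda
  chi <- qchisq(p, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * chi, 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2), 2 * genomic_lambda(p), tolerance = 1e-10)
})

test_that("clumping is hand-traceable on three SNVs", {
  st <- as_summary_stats(data.frame(
    chrom = "1", pos = c(1e6, 1.1e6, 2e6), rsid = c("a", "b", "c"),
    ea = "G", nea = "A", beta = 0.1, se = 0.05,
    p = c(1e-6, 1e-5, 1e-5), eaf = NA))
  cl <- clump(st, p_threshold = 1e-4, window_bp = 3e5)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$pos, c(1e6, 2e6))
  expect_equal(cl$n_members, c(2, 1))
  # single SNV: one locus
  expect_equal(nrow(clump(st[1, ])), 1)
})

test_that("clumping matches an exhaustive reference on 200 random SNVs", {
  set.seed(62)
  n <- 200
  st <- as_summary_stats(data.frame(
    chrom = sample(c("1", "2"), n, TRUE), pos = sample.int(5e6, n),
    rsid = paste0("rs", 1:n), ea = "G", nea = "A", beta = 0, se = 1,
    p = runif(n)^3, eaf = NA))
  win <- 2e5; thr <- 0.05
  cl <- clump(st, p_threshold = thr, window_bp = win)
  # reference: literal greedy re-implementation over explicit sets
  cand <- which(st$p < thr)
  cand <- cand[order(st$p[cand], st$chrom[cand], st$pos[cand])]
  leads <- integer(0); left <- cand
  while (length(left)) {
    lead <- left[1]
    leads <- c(leads, lead)
    drop <- left[st$chrom[left] == st$chrom[lead] &
                   abs(st$pos[left] - st$pos[lead]) <= win]
    left <- setdiff(left, drop)
  }
  expect_equal(cl$pos, st$pos[leads])
  expect_equal(cl$p, st$p[leads])
  # loci disjoint; union of members = all candidates
  members <- attr(cl, "members")
  expect_equal(anyDuplicated(unlist(members)), 0)
  expect_setequal(unlist(members), which(st$p < thr))
  # lead p <= member p within each locus
  for (mem in members) expect_true(all(st$p[mem[1]] <= st$p[mem]))
})

test_that("locus replication respects the 300 kb boundary in both directions", {
  catalog <- structure(data.frame(chrom = "1", pos = 1e6, rsid = "rsK",
                                  locus = "LOC1", stringsAsFactors = FALSE),
                       class = c("known_loci", "data.frame"))
  lead_at <- function(pos) data.frame(chrom = "1", pos = pos, rsid = "x",
                                      p = 1e-6)
  expect_equal(replicate_loci(lead_at(1e6 + 299999), catalog)$n_replicated, 1)
  expect_equal(replicate_loci(lead_at(1e6 - 299999), catalog)$n_replicated, 1)
  expect_equal(replicate_loci(lead_at(1e6 + 300001), catalog)$n_replicated, 0)
  expect_equal(replicate_loci(lead_at(1e6 - 300001), catalog)$n_replicated, 0)
})

test_that("planted catalog overlaps are recovered exactly and deduplicated", {
  set.seed(63)
  catalog <- structure(data.frame(
    chrom = as.character(rep(1:4, each = 5)),
    pos = rep(seq(1e6, 9e6, by = 2e6), 4) + sample.int(1e4, 20),
    rsid = paste0("k", 1:20),
    locus = paste0("LOC", rep(1:10, each = 2)),  # two SNVs per locus label
    stringsAsFactors = FALSE), class = c("known_loci", "data.frame"))
  hit <- catalog[c(1, 5, 12), ]
  leads <- data.frame(chrom = c(hit$chrom, "9", "9"),
                      pos = c(hit$pos + c(100, -2e5, 0), 5e6, 6e6),
                      rsid = paste0("L", 1:5), p = 1e-5)
  res <- replicate_loci(leads, catalog)
  expect_equal(sort(res$replicated_loci), sort(unique(hit$locus)))
  expect_equal(nrow(res$unmatched), 2)
  expect_equal(res$n_catalog_loci, 10)
})

test_that("exact-match replication applies the Bonferroni threshold", {
  make_stats <- function(n, p) as_summary_stats(data.frame(
    chrom = "1", pos = seq_len(n) * 1000, rsid = paste0("rs", seq_len(n)),
    ea = "G", nea = "A", beta = 0, se = 1, p = p, eaf = NA))
  catalog <- structure(data.frame(chrom = "1", pos = (1:771) * 1000,
                                  rsid = paste0("rs", 1:771), locus = "L",
                                  stringsAsFactors = FALSE),
                       class = c("known_loci", "data.frame"))
  st <- make_stats(900, runif(900, 0.2, 1))
  res <- exact_match_replication(st, catalog, alpha = 0.05)
  expect_equal(res$n_overlap, 771)
  expect_equal(res$bonferroni_threshold, 0.05 / 771)
  expect_equal(signif(res$bonferroni_threshold, 3), 6.49e-5)
  # alpha 0.05, one SNV -> threshold 0.05
  res1 <- exact_match_replication(make_stats(1, 0.5), catalog[1, ])
  expect_equal(res1$bonferroni_threshold, 0.05)
  expect_error(exact_match_replication(make_stats(1, 0.5), catalog[500, ]),
               "no overlap")
  # about 1% of null SNVs fall below the nominal 0.01 cutoff
  set.seed(64)
  hits <- replicate(200, {
    st0 <- make_stats(100, runif(100))
    nrow(exact_match_replication(st0, catalog, secondary_p = 0.01)$nominal)
  })
  expect_equal(mean(hits), 1, tolerance = 0.25)
})

test_that("fixed-effect meta-analysis pools by inverse variance", {
  mk <- function(beta, se, ea = "G", nea = "A") as_summary_stats(data.frame(
    chrom = "1", pos = 1000L, rsid = "rs1", ea = ea, nea = nea,
    beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), eaf = 0.3))
  m <- meta_fixed(list(mk(0.1, 0.1), mk(0.3, 0.1)))
  expect_equal(m$beta, 0.2)
  expect_equal(m$se, sqrt(1 / (100 + 100)), tolerance = 1e-12)
  # single study is the identity
  one <- meta_fixed(list(mk(0.12, 0.05)))
  expect_equal(one$beta, 0.12)
  expect_equal(one$se, 0.05)
  # allele flip: swapped EA/NEA contributes with negated beta
  fl <- meta_fixed(list(mk(0.1, 0.1), mk(-0.3, 0.1, ea = "A", nea = "G")))
  expect_equal(fl$beta, 0.2)
  # irreconcilable alleles error
  expect_error(meta_fixed(list(mk(0.1, 0.1), mk(0.1, 0.1, ea = "T", nea = "A"))),
               "irreconcilable")
  expect_error(meta_fixed(list(transform(mk(0.1, 0.1), se = -1))), "SE")
})

test_that("meta-analysis matches a WLS oracle to 1e-12 and shrinks the SE", {
  set.seed(65)
  n_var <- 12
  studies <- lapply(1:5, function(s) as_summary_stats(data.frame(
    chrom = "1", pos = (1:n_var) * 1000L, rsid = paste0("rs", 1:n_var),
    ea = "G", nea = "A", beta = rnorm(n_var, 0.1, 0.2),
    se = runif(n_var, 0.02, 0.3), p = 0.5, eaf = 0.3)))
  m <- meta_fixed(studies)
  for (i in seq_len(n_var)) {
    b <- vapply(studies, function(s) s$beta[i], numeric(1))
    se <- vapply(studies, function(s) s$se[i], numeric(1))
    # oracle: weighted least squares of betas on an intercept
    w <- 1 / se^2
    fit <- lm(b ~ 1, weights = w)
    expect_equal(m$beta[i], unname(coef(fit)[1]), tolerance = 1e-12)
    expect_equal(m$se[i], 1 / sqrt(sum(w)), tolerance = 1e-12)
    expect_lt(m$se[i], min(se))
    expect_gte(m$beta[i], min(b)); expect_lte(m$beta[i], max(b))
  }
})

test_that("meta-analysis agrees with metafor's fixed-effect pooling", {
  skip_if_not_installed("metafor")
  set.seed(66)
  b <- rnorm(4, 0.2, 0.1); se <- runif(4, 0.05, 0.2)
  studies <- lapply(1:4, function(s) as_summary_stats(data.frame(
    chrom = "1", pos = 1000L, rsid = "rs1", ea = "G", nea = "A",
    beta = b[s], se = se[s], p = 0.5, eaf = NA)))
  m <- meta_fixed(studies)
  ref <- metafor::rma(yi = b, sei = se, method = "FE")
  expect_equal(m$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(m$se, ref$se, tolerance = 1e-10)
})
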