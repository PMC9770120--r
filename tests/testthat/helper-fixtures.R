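# tiny in-code fixtures shared across test files

mini_variants <- function() {
  variant_keys(chrom = c("1", "2"), pos = c(1000, 2000),
               ref = c("A", "C"), alt = c("G", "T"),
               rsid = c("rs1", "rs2"))
}

mini_geno <- function() {
  genotype_matrix(rbind(c(0, 1), c(1, 2), c(NA, 0)),
                  c("s1", "s2", "s3"), mini_variants())
}

mini_scoring <- function(weights = c(0.5, -0.2),
                         effect = c("G", "T"), other = c("A", "C")) {
  structure(data.frame(rsid = c("rs1", "rs2"), chrom = c("1", "2"),
                       pos = c(1000L, 2000L),
                       effect_allele = effect, other_allele = other,
                       weight = weights, stringsAsFactors = FALSE),
            pgs_id = "PGSTEST", class = c("scoring_file", "data.frame"))
}

mini_cohort <- function(status = c("case", "control", "control"),
                        n = length(status)) {
  as_cohort_table(data.frame(
    sample_id = sprintf("s%d", seq_len(n)),
    status = rep_len(status, n),
    age = seq(40, 60, length.out = n),
    sex = rep_len(c("male", "female"), n),
    ancestry = rep_len(c("anc1", "anc2"), n),
    stringsAsFactors = FALSE))
}

random_geno <- function(n, m, maf = NULL, miss = 0, seed = 1) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  if (miss > 0) d[runif(n * m) < miss] <- NA
  genotype_matrix(d, sprintf("s%d", seq_len(n)),
                  variant_keys(rep("1", m), seq_len(m) * 100,
                               rep("A", m), rep("G", m)))
}

# brute-force AUC by pair counting (oracle)
auc_bruteforce <- function(cases, controls) {
  s <- 0
  for (x in cases) for (y in controls)
    s <- s + (x > y) + 0.5 * (x == y)
  s / (length(cases) * length(controls))
}
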