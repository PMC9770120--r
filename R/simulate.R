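#' Configuration for a synthetic case-control cohort
#'
#' The defaults describe a multi-ancestry coronary-disease-like
#' case-control study at one seventh of the motivating cohort's size
#' (145 cases / 860 controls, case fraction ~1/7), with three ancestry
#' strata differentiated at Fst 0.05, a polygenic liability whose
#' odds ratio per SD is 1.8, cases older and more often male than
#' controls, four lipid genes carrying an excess rare-variant burden in
#' cases, and a 7-SNV haplotype block with a protective haplotype at
#' frequency 0.17 in cases versus 0.213 in controls. Pass
#' `full_scale = TRUE` for the 1014 / 6009 cohort size.
#'
#' @param n_cases,n_controls Target group sizes (expected counts; case
#'   status is drawn from the liability model, so realized counts vary
#'   binomially around these).
#' @param n_common_variants Number of common variants to simulate.
#' @param n_ancestries Number of ancestry strata.
#' @param mixing Ancestry proportions (sum 1).
#' @param fst Balding-Nichols differentiation parameter, in (0, 1).
#' @param beta_prs Log odds ratio per SD of the true polygenic score.
#' @param beta_age Log odds ratio per year of age (centered).
#' @param beta_sex Log odds ratio for male vs female.
#' @param n_pcs Number of genotype principal components in the cohort table.
#' @param rare_genes data.frame with columns `gene`, `case_rate`,
#'   `control_rate` (per-sample carrier probabilities), `impact`.
#' @param n_rare_per_gene Rare variants per gene among which carriers are
#'   spread.
#' @param plant_control_singleton Add one moderate-impact variant carried
#'   by exactly one control, so the minimum nonzero control MAF (the
#'   pseudo-CCR denominator) is well defined.
#' @param hap_pool Character vector of haplotype strings (equal length).
#' @param hap_freq_cases,hap_freq_controls Frequencies per haplotype,
#'   each summing to 1.
#' @param full_scale Use the full 1014 / 6009 cohort size.
#' @param seed Integer seed; every generator is a pure function of
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 145, n_controls = 860,
                       n_common_variants = 200,
                       n_ancestries = 3,
                       mixing = c(0.5, 0.35, 0.15),
                       fst = 0.05,
                       beta_prs = log(1.8),
                       beta_age = 0.1,
                       beta_sex = 1.1,
                       n_pcs = 4,
                       rare_genes = data.frame(
                         gene = c("LDLR", "APOB", "PCSK9", "ANGPTL4"),
                         case_rate = c(0.009, 0.012, 0.005, 0.006),
                         control_rate = c(0.0015, 0.0027, 0.0028, 0.001),
                         impact = "high"),
                       n_rare_per_gene = 5,
                       plant_control_singleton = TRUE,
                       hap_pool = c("CCAAATT", "TTGGGAC", "CTGAATC", "TCAGGAC"),
                       hap_freq_cases = c(0.17, 0.42, 0.26, 0.15),
                       hap_freq_controls = c(0.213, 0.387, 0.26, 0.14),
                       full_scale = FALSE,
                       seed = 1) {
  if (full_scale) { n_cases <- 1014; n_controls <- 6009 }
  mixing <- rep_len(mixing, n_ancestries)
  stopifnot(fst > 0, fst < 1, n_cases > 0, n_controls > 0,
            abs(sum(mixing) - 1) < 1e-8,
            all(rare_genes$case_rate >= 0 & rare_genes$case_rate <= 1),
            all(rare_genes$control_rate >= 0 & rare_genes$control_rate <= 1),
            length(hap_pool) == length(hap_freq_cases),
            length(hap_pool) == length(hap_freq_controls),
            abs(sum(hap_freq_cases) - 1) < 1e-8,
            abs(sum(hap_freq_controls) - 1) < 1e-8,
            length(unique(nchar(hap_pool))) == 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_total = n_cases + n_controls,
                 case_fraction = n_cases / (n_cases + n_controls),
                 n_common_variants = n_common_variants,
                 n_ancestries = n_ancestries, mixing = mixing, fst = fst,
                 beta_prs = beta_prs, beta_age = beta_age,
                 beta_sex = beta_sex, n_pcs = n_pcs,
                 rare_genes = rare_genes, n_rare_per_gene = n_rare_per_gene,
                 plant_control_singleton = plant_control_singleton,
                 hap_pool = hap_pool, hap_freq_cases = hap_freq_cases,
                 hap_freq_controls = hap_freq_controls,
                 seed = as.integer(seed)),
            class = "sim_config")
}

random_variant_keys <- function(n, chrom_pool = as.character(1:22)) {
  bases <- c("A", "C", "G", "T")
  repeat {
    chrom <- sample(chrom_pool, n, replace = TRUE)
    pos <- sample.int(2.5e8, n, replace = TRUE)
    if (!anyDuplicated(paste(chrom, pos))) break
  }
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variant_keys(chrom, pos, ref, alt, paste0("rs", sample.int(1e8, n)))
}

#' Simulate common genotypes under the Balding-Nichols model
#'
#' Each variant draws an ancestral frequency p ~ Uniform(0.05, 0.95);
#' each ancestry stratum then draws its own frequency from
#' Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst), and genotypes are
#' Binomial(2, freq) within stratum — the simplest model with a single
#' differentiation knob emulating a multi-ancestry cohort.
#'
#' @param config A `sim_config`.
#' @return List with `geno` (a `genotype_matrix`), `ancestry` (per-sample
#'   stratum label), `ancestral_freq`, `freq` (strata x variants matrix).
#' @export
sim_common_genotypes <- function(config) {
  local_seed(config$seed, {
    n <- config$n_total; m <- config$n_common_variants
    k <- config$n_ancestries
    anc_levels <- paste0("anc", seq_len(k))
    ancestry <- sample(anc_levels, n, replace = TRUE, prob = config$mixing)
    p_anc <- stats::runif(m, 0.05, 0.95)
    fst <- config$fst
    freq <- matrix(stats::rbeta(k * m,
                                rep(p_anc, each = k) * (1 - fst) / fst,
                                rep(1 - p_anc, each = k) * (1 - fst) / fst),
                   nrow = k)
    freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
    dos <- matrix(0, n, m)
    ai <- match(ancestry, anc_levels)
    for (a in seq_len(k)) {
      rows <- which(ai == a)
      if (length(rows))
        dos[rows, ] <- matrix(stats::rbinom(length(rows) * m, 2,
                                            rep(freq[a, ], each = length(rows))),
                              nrow = length(rows))
    }
    geno <- genotype_matrix(dos, sprintf("S%05d", seq_len(n)),
                            random_variant_keys(m))
    list(geno = geno, ancestry = ancestry, ancestral_freq = p_anc,
         freq = freq, anc_levels = anc_levels)
  })
}

#' Simulate phenotypes and covariates from a liability model
#'
#' True polygenic weights are drawn N(0, 1/m); the true PRS is the
#' standardized weighted dosage sum. Case probability follows
#' logistic(b0 + beta_prs z + beta_age (age - mean age) + beta_sex male),
#' with b0 tuned by bisection so the expected case fraction matches the
#' configured one to within 0.5%. Ages and sexes are drawn from common
#' population distributions; with the default positive age and male
#' effects, simulated cases come out older and more often male than
#' controls, mirroring the covariate imbalance typical of cardiac
#' case-control studies. Principal components are computed from the
#' simulated genotypes.
#'
#' @param geno_sim Output of [sim_common_genotypes()].
#' @param config The `sim_config`.
#' @return List with `cohort` (a `cohort_table`), `true_prs` (a
#'   standardized `prs_vector`), `true_weights`, `intercept`,
#'   `case_prob`.
#' @export
sim_phenotypes <- function(geno_sim, config) {
  local_seed(config$seed + 1L, {
    geno <- geno_sim$geno
    n <- length(geno$sample_ids)
    m <- ncol(geno$dosage)
    w <- stats::rnorm(m, 0, sqrt(1 / m))
    raw <- as.numeric(geno$dosage %*% w)
    if (stats::sd(raw) == 0) stop("degenerate genotype matrix: constant PRS")
    z <- (raw - mean(raw)) / stats::sd(raw)
    age <- pmin(pmax(stats::rnorm(n, 45, 13), 20), 85)
    sex <- ifelse(stats::runif(n) < 0.47, "male", "female")
    bmi <- pmin(pmax(stats::rnorm(n, 28.5, 5), 15), 50)
    lin <- config$beta_prs * z + config$beta_age * (age - mean(age)) +
      config$beta_sex * (sex == "male")
    target <- config$case_fraction
    f <- function(b0) mean(stats::plogis(b0 + lin)) - target
    lo <- -30; hi <- 30
    if (f(lo) > 0 || f(hi) < 0)
      stop("configured case fraction unattainable under the liability model")
    b0 <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
    p <- stats::plogis(b0 + lin)
    if (abs(mean(p) - target) > 0.005)
      stop("bisection failed to hit the configured case fraction")
    status <- ifelse(stats::runif(n) < p, "case", "control")
    pcs <- NULL
    if (config$n_pcs > 0) {
      pc <- stats::prcomp(geno$dosage, center = TRUE, scale. = FALSE)
      pcs <- pc$x[, seq_len(min(config$n_pcs, ncol(pc$x))), drop = FALSE]
      colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))
    }
    cohort <- data.frame(sample_id = geno$sample_ids, status = status,
                         age = age, sex = sex, bmi = bmi,
                         ancestry = geno_sim$ancestry,
                         stringsAsFactors = FALSE)
    if (!is.null(pcs)) cohort <- cbind(cohort, as.data.frame(pcs))
    cohort <- as_cohort_table(cohort)
    true_prs <- prs_vector(geno$sample_ids, raw, z = z, pgs_id = "truePRS",
                           scope = "overall")
    list(cohort = cohort, true_prs = true_prs, true_weights = w,
         intercept = b0, case_prob = p)
  })
}

#' Simulate rare variants with differential case/control burden
#'
#' Per gene, each sample becomes a carrier with its group's configured
#' rate; carriers are assigned one heterozygous variant, drawn uniformly
#' among the gene's variants. Optionally one extra moderate-impact
#' variant carried by a single control is planted so the minimum nonzero
#' control MAF — the pseudo-CCR denominator — exists by construction.
#'
#' @param config A `sim_config`.
#' @param cohort A `cohort_table` giving case status.
#' @return List with `geno` (a `genotype_matrix`) and `annot` (a
#'   `variant_annotation`).
#' @export
sim_rare_variants <- function(config, cohort) {
  local_seed(config$seed + 2L, {
    n <- nrow(cohort)
    case <- cohort$status == "case"
    genes <- config$rare_genes
    nv <- config$n_rare_per_gene
    total_v <- nrow(genes) * nv + as.integer(config$plant_control_singleton)
    dos <- matrix(0, n, total_v)
    gene_lab <- character(total_v)
    impact <- character(total_v)
    col <- 0L
    for (g in seq_len(nrow(genes))) {
      rate <- ifelse(case, genes$case_rate[g], genes$control_rate[g])
      carrier <- stats::runif(n) < rate
      which_v <- sample.int(nv, sum(carrier), replace = TRUE)
      for (vi in seq_len(nv)) {
        col <- col + 1L
        dos[which(carrier)[which_v == vi], col] <- 1
        gene_lab[col] <- genes$gene[g]
        impact[col] <- genes$impact[g]
      }
    }
    if (config$plant_control_singleton) {
      col <- col + 1L
      ctrl <- which(!case)
      if (length(ctrl)) dos[ctrl[1], col] <- 1
      gene_lab[col] <- genes$gene[1]
      impact[col] <- "moderate"
    }
    vk <- random_variant_keys(total_v, chrom_pool = "19")
    geno <- genotype_matrix(dos, cohort$sample_id, vk)
    annot <- as_variant_annotation(data.frame(
      chrom = vk$chrom, pos = vk$pos, ref = vk$ref, alt = vk$alt,
      gene = gene_lab, impact = impact, clinvar = "none",
      stringsAsFactors = FALSE))
    list(geno = geno, annot = annot)
  })
}

#' Simulate an unphased haplotype block
#'
#' Each sample draws two haplotypes i.i.d. from its group's pool; the
#' returned genotypes are per-site alternate-allele sums, phase
#' discarded. Site ref/alt alleles are taken from the pool: ref is the
#' allele of the first pool haplotype at that site, alt the other
#' observed allele.
#'
#' @param config A `sim_config`.
#' @param cohort A `cohort_table` giving case status.
#' @return List with `geno` (a `genotype_matrix` over k SNVs),
#'   `true_freq_cases`, `true_freq_controls` (named by haplotype string).
#' @export
sim_haplotypes <- function(config, cohort) {
  local_seed(config$seed + 3L, {
    pool <- config$hap_pool
    k <- nchar(pool[1])
    alle <- do.call(rbind, strsplit(pool, ""))
    ref <- alle[1, ]
    alt <- vapply(seq_len(k), function(s) {
      others <- setdiff(unique(alle[, s]), ref[s])
      if (!length(others)) setdiff(c("A", "C", "G", "T"), ref[s])[1] else others[1]
    }, character(1))
    if (any(apply(alle, 2, function(a) length(unique(a))) > 2))
      stop("haplotype pool implies more than two alleles at a site")
    hap_bits <- t(apply(alle, 1, function(a) as.integer(a == alt)))
    n <- nrow(cohort)
    case <- cohort$status == "case"
    pick <- function(nn, fr) sample.int(length(pool), 2 * nn, replace = TRUE, prob = fr)
    draws <- integer(2 * n)
    draws[rep(case, each = 2)] <- pick(sum(case), config$hap_freq_cases)
    draws[rep(!case, each = 2)] <- pick(sum(!case), config$hap_freq_controls)
    h1 <- draws[seq(1, 2 * n, by = 2)]
    h2 <- draws[seq(2, 2 * n, by = 2)]
    dos <- hap_bits[h1, , drop = FALSE] + hap_bits[h2, , drop = FALSE]
    vk <- variant_keys(rep("9", k), 22088000 + seq_len(k) * 1000, ref, alt,
                       paste0("hs", seq_len(k)))
    geno <- genotype_matrix(dos, cohort$sample_id, vk)
    list(geno = geno,
         true_freq_cases = stats::setNames(config$hap_freq_cases, pool),
         true_freq_controls = stats::setNames(config$hap_freq_controls, pool))
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [sim_common_genotypes()],
#' [sim_phenotypes()], [sim_rare_variants()] and [sim_haplotypes()] in
#' sequence from one configuration.
#'
#' @param config A `sim_config`.
#' @return List with `geno`, `cohort`, `true_prs`, `true_weights`,
#'   `rare` (geno + annot), `hap` (geno + true frequencies), `config`.
#' @export
sim_cohort <- function(config = sim_config()) {
  gs <- sim_common_genotypes(config)
  ph <- sim_phenotypes(gs, config)
  rare <- sim_rare_variants(config, ph$cohort)
  hap <- sim_haplotypes(config, ph$cohort)
  list(geno = gs$geno, ancestry = gs$ancestry, cohort = ph$cohort,
       true_prs = ph$true_prs, true_weights = ph$true_weights,
       rare = rare, hap = hap, config = config)
}

#' Write a simulated cohort out as analysis-ready fixture files
#'
#' Emits a VCF of common genotypes, a cohort TSV, a scoring file built
#' from the true polygenic weights, the rare-variant VCF and annotation
#' TSV, and the haplotype-block VCF, into `dir`.
#'
#' @param sim Output of [sim_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
write_sim_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "common.vcf"),
    cohort = file.path(dir, "cohort.tsv"),
    scoring = file.path(dir, "scoring.txt"),
    rare_vcf = file.path(dir, "rare.vcf"),
    annot = file.path(dir, "rare_annotation.tsv"),
    hap_vcf = file.path(dir, "haplotype.vcf")
  )
  write_vcf(sim$geno, paths["vcf"])
  write_cohort_table(sim$cohort, paths["cohort"])
  v <- sim$geno$variants
  scoring <- structure(data.frame(rsid = v$rsid, chrom = v$chrom, pos = v$pos,
                                  effect_allele = v$alt, other_allele = v$ref,
                                  weight = sim$true_weights,
                                  stringsAsFactors = FALSE),
                       pgs_id = "truePRS",
                       class = c("scoring_file", "data.frame"))
  write_scoring_file(scoring, paths["scoring"])
  write_vcf(sim$rare$geno, paths["rare_vcf"])
  write_variant_annotation(sim$rare$annot, paths["annot"])
  write_vcf(sim$hap$geno, paths["hap_vcf"])
  paths
}
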