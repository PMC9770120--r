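test_that("variant keys enforce positional and allele invariants", {
  expect_error(variant_keys("1", 0, "A", "G"), "1-based")
  expect_error(variant_keys("1", 100, "A", "A"), "differ")
  expect_error(variant_keys("1", 100, "<DEL>", "A"), "symbolic")
  v <- variant_keys("1", 100, "a", "g")
  expect_equal(v$ref, "A")   # uppercased
})

test_that("GT fields map to dosages: 0/1 -> 1, ./. -> missing", {
  g <- mini_geno()
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, tmp)
  lines <- readLines(tmp)
  expect_true(any(grepl("0/1", lines)))
  expect_true(any(grepl("\\./\\.", lines)))
  back <- read_vcf(tmp)
  expect_equal(back$dosage, g$dosage)
  expect_equal(back$sample_ids, g$sample_ids)
  expect_equal(back$variants$pos, g$variants$pos)
})

test_that("VCF round-trips a simulated fixture and honors sample subsets", {
  sim <- sim_common_genotypes(sim_config(n_cases = 5, n_controls = 20,
                                         n_common_variants = 12, seed = 11))
  tmp <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$geno, tmp)
  back <- read_vcf(tmp)
  expect_identical(back$dosage, sim$geno$dosage)
  sub <- read_vcf(tmp, sample_subset = c("S00003", "S00001"))
  expect_equal(sub$sample_ids, c("S00003", "S00001"))
  expect_equal(sub$dosage["S00001", ], sim$geno$dosage["S00001", ])
})

test_that("read_vcf rejects malformed GT and duplicate variant records", {
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
             "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/2")
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, tmp)
  expect_error(read_vcf(tmp), "malformed GT")
  lines[4] <- "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"
  writeLines(c(lines, lines[4]), tmp)
  expect_error(read_vcf(tmp), "duplicate")
})

test_that("scoring files parse, report malformed rows, and round-trip", {
  txt <- c("#pgs_id=PGS999",
           "rsID\tchr_name\tchr_position\teffect_allele\tother_allele\teffect_weight",
           "rs1\t1\t1000\tG\tA\t0.5",
           "rs2\t2\t2000\tT\tC\t-0.2")
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(txt, tmp)
  sc <- read_scoring_file(tmp)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$weight, c(0.5, -0.2))
  expect_equal(attr(sc, "pgs_id"), "PGS999")

  writeLines(c(txt, "rs3\t3\t3000\tG\tA\tnot_a_number"), tmp)
  expect_warning(sc2 <- read_scoring_file(tmp), "1 scoring record")
  expect_equal(nrow(sc2), 2)

  writeLines(c(txt[1:2], "rs3\t3\t3000\t\t\tx"), tmp)
  expect_error(suppressWarnings(read_scoring_file(tmp)), "no parseable")

  tmp2 <- withr::local_tempfile(fileext = ".txt")
  write_scoring_file(sc, tmp2)
  sc3 <- read_scoring_file(tmp2)
  expect_equal(sc3$weight, sc$weight)
  expect_equal(sc3$effect_allele, sc$effect_allele)
})

test_that("cohort, summary-stats and known-loci tables round-trip with validation", {
  co <- mini_cohort(n = 6)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_table(co, tmp)
  expect_equal(as.data.frame(read_cohort_table(tmp)), as.data.frame(co))
  bad <- co; bad$status[1] <- "maybe"
  expect_error(as_cohort_table(bad), "status")

  ss <- as_summary_stats(data.frame(
    chrom = "1", pos = c(100L, 200L), rsid = c("rs1", "rs2"),
    ea = c("G", "T"), nea = c("A", "C"), beta = c(0.1, -0.2),
    se = c(0.05, 0.04), p = c(0.04, 1e-6), eaf = c(0.3, 0.2)))
  write_summary_stats(ss, tmp)
  expect_equal(as.data.frame(read_summary_stats(tmp)), as.data.frame(ss))
  expect_error(as_summary_stats(transform(ss, se = 0)), "positive")

  kl <- data.frame(chrom = c("1", "1"), pos = c(100L, 100L),
                   rsid = "rs1", locus = "LOC1")
  write_known_loci(kl, tmp)
  expect_equal(nrow(read_known_loci(tmp)), 1)  # deduplicated on (chrom, pos)
})

test_that("harmonize orients, strand-flips, drops, and is idempotent", {
  g <- mini_geno()
  h <- harmonize(mini_scoring(), g)
  expect_equal(h$orientation, c(1, 1))

  # effect allele = ref: dosage complemented
  h2 <- harmonize(mini_scoring(effect = c("A", "C"), other = c("G", "T")), g)
  expect_equal(h2$orientation, c(-1, -1))
  p2 <- score_samples(g, h2)
  expect_equal(p2$raw[2], 0.5 * (2 - 1) + (-0.2) * (2 - 2))

  # strand complement: effect C/other T is complement of G/A at variant 1
  h3 <- harmonize(mini_scoring(effect = c("C", "A"), other = c("T", "G")), g)
  expect_true(all(h3$strand_flipped))
  expect_equal(h3$orientation, c(1, 1))

  # unmatched records dropped and counted; zero matches error
  sc_miss <- mini_scoring()
  sc_miss$pos[2] <- 9999L
  h4 <- harmonize(sc_miss, g)
  expect_equal(h4$n_matched, 1)
  expect_equal(h4$n_unmatched, 1)
  sc_none <- mini_scoring(); sc_none$pos <- c(5L, 6L)
  expect_error(harmonize(sc_none, g), "zero")

  # ambiguous A/T pair dropped only under the flag
  g_at <- genotype_matrix(matrix(c(0, 1, 2), 3, 1), c("s1", "s2", "s3"),
                          variant_keys("1", 1000, "A", "T"))
  sc_at <- mini_scoring(effect = c("T", "T"), other = c("A", "C"))[1, ]
  class(sc_at) <- c("scoring_file", "data.frame"); attr(sc_at, "pgs_id") <- "x"
  expect_equal(harmonize(sc_at, g_at)$n_matched, 1)
  expect_error(harmonize(sc_at, g_at, drop_ambiguous = TRUE), "zero")
})

test_that("swapping effect/other alleles and negating weights shifts scores by 2*sum(w)", {
  sim <- sim_common_genotypes(sim_config(n_cases = 10, n_controls = 40,
                                         n_common_variants = 30, seed = 5))
  g <- sim$geno
  v <- g$variants
  sc <- structure(data.frame(rsid = v$rsid, chrom = v$chrom, pos = v$pos,
                             effect_allele = v$alt, other_allele = v$ref,
                             weight = rnorm(nrow(v)), stringsAsFactors = FALSE),
                  pgs_id = "fwd", class = c("scoring_file", "data.frame"))
  swapped <- sc
  swapped$effect_allele <- sc$other_allele
  swapped$other_allele <- sc$effect_allele
  swapped$weight <- -sc$weight
  s1 <- score_samples(g, sc)$raw
  s2 <- score_samples(g, swapped)$raw
  # sum w_i d_i = sum(-w_i)(2 - d_i) + 2 sum w_i
  expect_equal(s1, s2 + 2 * sum(sc$weight), tolerance = 1e-12)
})

test_that("dosage complement is an involution through double swap", {
  g <- mini_geno()
  sc <- mini_scoring()
  h_fwd <- harmonize(sc, g)
  sc_swap <- sc
  sc_swap$effect_allele <- sc$other_allele
  sc_swap$other_allele <- sc$effect_allele
  h_swap <- harmonize(sc_swap, g)
  expect_equal(h_swap$orientation, -h_fwd$orientation)
  sc_back <- sc_swap
  sc_back$effect_allele <- sc_swap$other_allele
  sc_back$other_allele <- sc_swap$effect_allele
  h_back <- harmonize(sc_back, g)
  expect_identical(h_back$orientation, h_fwd$orientation)
})
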