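#' Construct a validated variant key table
#'
#' Variants are identified positionally by (chrom, pos, ref, alt), the VCF
#' convention, with 1-based positions. rsIDs are carried as advisory
#' annotation only and never used for matching within the package.
#'
#' @param chrom Chromosome labels (character).
#' @param pos 1-based positions (integer-valued).
#' @param ref Reference allele strings over A/C/G/T.
#' @param alt Alternate allele strings over A/C/G/T.
#' @param rsid Optional identifiers (`NA` allowed).
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `rsid`.
#' @export
variant_keys <- function(chrom, pos, ref, alt, rsid = NA_character_) {
  n <- length(chrom)
  v <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = toupper(as.character(ref)),
    alt = toupper(as.character(alt)),
    rsid = rep_len(as.character(rsid), n),
    stringsAsFactors = FALSE
  )
  if (any(is.na(v$pos)) || any(v$pos < 1L))
    stop("variant positions must be 1-based integers >= 1")
  bad <- !grepl("^[ACGT]+$", v$ref) | !grepl("^[ACGT]+$", v$alt)
  if (any(bad))
    stop("alleles must be non-symbolic strings over {A,C,G,T}; offending variant(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(v$ref == v$alt))
    stop("ref and alt alleles must differ")
  v
}

vk_id <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Construct a genotype matrix
#'
#' @param dosage Numeric matrix, samples in rows, variants in columns;
#'   entries in {0, 1, 2} or `NA` (missing genotype). Dosages count the
#'   ALT allele of the corresponding variant.
#' @param sample_ids Character vector of sample identifiers.
#' @param variants Variant key table as from [variant_keys()].
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sample_ids, variants) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) != length(sample_ids))
    stop("dosage rows (", nrow(dosage), ") != number of samples (",
         length(sample_ids), ")")
  if (ncol(dosage) != nrow(variants))
    stop("dosage columns (", ncol(dosage), ") != number of variants (",
         nrow(variants), ")")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok))
    stop("dosage entries must be 0, 1, 2 or NA")
  ids <- vk_id(variants)
  if (anyDuplicated(ids))
    stop("duplicate variant key(s): ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  dimnames(dosage) <- list(as.character(sample_ids), ids)
  structure(list(dosage = dosage,
                 sample_ids = as.character(sample_ids),
                 variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "variants;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Per-variant missingness rate
#' @param geno A `genotype_matrix`.
#' @return Named numeric vector, one rate per variant.
#' @export
missingness <- function(geno) colMeans(is.na(geno$dosage))

#' Read genotypes from a VCF file
#'
#' Reads GT fields of a biallelic VCF (v4.2) into an ALT-allele dosage
#' matrix. Any GT containing a missing allele ('.') becomes a missing
#' dosage. Multiallelic records must be split upstream (e.g. with
#' `bcftools norm -m -`).
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @param sample_subset Optional character vector of sample IDs to keep,
#'   in the requested order.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  variants <- variant_keys(fix[, "CHROM"], as.integer(fix[, "POS"]),
                           fix[, "REF"], fix[, "ALT"],
                           ifelse(fix[, "ID"] == ".", NA, fix[, "ID"]))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (!is.null(sample_subset)) {
    miss <- setdiff(sample_subset, colnames(gt))
    if (length(miss)) stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }
  ok <- is.na(gt) | grepl("^[01.]([/|][01.])?$", gt)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed GT '", gt[bad[1], bad[2]], "' at record ",
         vk_id(variants[bad[1], ]), " sample ", colnames(gt)[bad[2]])
  }
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  measurable <- !is.na(gt) & !grepl("\\.", gt)
  dos[measurable] <- vapply(strsplit(gt[measurable], "[/|]"),
                            function(a) sum(a == "1"), numeric(1))
  genotype_matrix(t(dos), colnames(gt), variants)
}

#' Write a genotype matrix as a minimal VCF v4.2 file
#'
#' Inverse of [read_vcf()] for fixtures and simulator output: unphased
#' GTs, missing dosage written as './.'.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- geno$dosage
  body <- vapply(seq_len(nrow(v)), function(i) {
    g <- d[, i]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(v$chrom[i], v$pos[i],
            ifelse(is.na(v$rsid[i]), ".", v$rsid[i]),
            v$ref[i], v$alt[i], ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", geno$sample_ids), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a PGS Catalog style scoring file
#'
#' Tab-separated with a header line; '#' lines are comments. Recognized
#' columns: `rsID`, `chr_name`, `chr_position`, `effect_allele`,
#' `other_allele`, `effect_weight`. Rows without a parseable effect weight
#' or effect allele are dropped with a warning giving the count.
#'
#' @param path Path to the scoring file.
#' @param pgs_id Score label; defaults to a `#pgs_id=` comment if present,
#'   else the file name without extension.
#' @return A `data.frame` of class `scoring_file` with columns `rsid`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `weight`, and
#'   attribute `pgs_id`.
#' @export
read_scoring_file <- function(path, pgs_id = NULL) {
  lines <- readLines(path)
  if (is.null(pgs_id)) {
    tag <- grep("^#\\s*pgs_id\\s*=", lines, value = TRUE)
    pgs_id <- if (length(tag)) sub("^#\\s*pgs_id\\s*=\\s*", "", tag[1])
              else sub("\\.[^.]*$", "", basename(path))
  }
  lines <- lines[!grepl("^#", lines)]
  if (!length(lines)) stop("no data lines in scoring file: ", path)
  tab <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  pick <- function(nm) if (nm %in% names(tab)) tab[[nm]] else rep(NA_character_, nrow(tab))
  out <- data.frame(
    rsid = pick("rsID"),
    chrom = pick("chr_name"),
    pos = suppressWarnings(as.integer(pick("chr_position"))),
    effect_allele = toupper(pick("effect_allele")),
    other_allele = toupper(pick("other_allele")),
    weight = suppressWarnings(as.numeric(pick("effect_weight"))),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$weight) | is.na(out$effect_allele) |
    !grepl("^[ACGT]+$", out$effect_allele)
  if (all(bad)) stop("no parseable scoring records in ", path)
  if (any(bad)) {
    warning(sum(bad), " scoring record(s) dropped (missing weight or effect allele)")
    out <- out[!bad, , drop = FALSE]
  }
  has_other <- !is.na(out$other_allele) & out$other_allele != ""
  if (any(has_other & out$other_allele == out$effect_allele))
    stop("effect_allele equals other_allele in scoring file ", path)
  rownames(out) <- NULL
  structure(out, pgs_id = pgs_id, class = c("scoring_file", "data.frame"))
}

#' Write a scoring file in the PGS Catalog dialect
#' @param scoring A `scoring_file`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(scoring, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#pgs_id=", attr(scoring, "pgs_id")), con)
  tab <- data.frame(rsID = scoring$rsid, chr_name = scoring$chrom,
                    chr_position = scoring$pos,
                    effect_allele = scoring$effect_allele,
                    other_allele = scoring$other_allele,
                    effect_weight = scoring$weight)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a cohort phenotype/covariate table
#'
#' Tab-separated with header. Required columns: `sample_id`, `status`
#' (case/control), `age`, `sex` (male/female). Optional: `bmi`,
#' `ancestry`, principal components `pc1`, `pc2`, ..., and any further
#' covariates (e.g. `t2d`), kept as-is.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  as_cohort_table(tab)
}

#' Validate a data frame as a cohort table
#' @param tab A data.frame with at least `sample_id`, `status`, `age`, `sex`.
#' @return The validated `cohort_table`.
#' @export
as_cohort_table <- function(tab) {
  need <- c("sample_id", "status", "age", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  if (!all(tab$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (any(!is.finite(tab$age)) || any(tab$age <= 0))
    stop("ages must be positive")
  if (!all(tab$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  structure(tab, class = c("cohort_table", "data.frame"))
}

#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' TSV with columns CHR, POS, RSID, EA, NEA, BETA, SE, P and optionally
#' EAF. BETA is the per-allele log odds ratio for the effect allele EA.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `summary_stats` with columns `chrom`,
#'   `pos`, `rsid`, `ea`, `nea`, `beta`, `se`, `p`, `eaf`.
#' @export
read_summary_stats <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("CHR", "POS", "RSID", "EA", "NEA", "BETA", "SE", "P")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("summary stats lack column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(chrom = as.character(tab$CHR), pos = as.integer(tab$POS),
                    rsid = as.character(tab$RSID),
                    ea = toupper(tab$EA), nea = toupper(tab$NEA),
                    beta = tab$BETA, se = tab$SE, p = tab$P,
                    eaf = if ("EAF" %in% names(tab)) tab$EAF else NA_real_,
                    stringsAsFactors = FALSE)
  as_summary_stats(out)
}

#' @export
as_summary_stats <- function(out) {
  if (any(out$se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  if (any(out$p <= 0 | out$p > 1, na.rm = TRUE)) stop("p-values must be in (0, 1]")
  structure(out, class = c("summary_stats", "data.frame"))
}

#' @export
write_summary_stats <- function(stats, path) {
  tab <- data.frame(CHR = stats$chrom, POS = stats$pos, RSID = stats$rsid,
                    EA = stats$ea, NEA = stats$nea, BETA = stats$beta,
                    SE = stats$se, P = stats$p, EAF = stats$eaf)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-loci catalog
#'
#' TSV with columns CHR, POS, RSID, LOCUS listing previously reported
#' SNVs and the locus/gene label each belongs to. Records duplicated on
#' (CHR, POS) are deduplicated.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` of class `known_loci` with columns `chrom`,
#'   `pos`, `rsid`, `locus`.
#' @export
read_known_loci <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("CHR", "POS", "RSID", "LOCUS")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("known-loci catalog lacks column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(chrom = as.character(tab$CHR), pos = as.integer(tab$POS),
                    rsid = as.character(tab$RSID), locus = as.character(tab$LOCUS),
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[, c("chrom", "pos")]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("known_loci", "data.frame"))
}

#' @export
write_known_loci <- function(catalog, path) {
  tab <- data.frame(CHR = catalog$chrom, POS = catalog$pos,
                    RSID = catalog$rsid, LOCUS = catalog$locus)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
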