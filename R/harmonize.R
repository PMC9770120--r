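comp_allele <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_ambiguous_pair <- function(a, b) {
  # strand-ambiguous SNP pairs: A/T or C/G in either order
  !is.na(b) & nchar(a) == 1 & nchar(b) == 1 & b == comp_allele(a)
}

#' Harmonize a scoring file against a genotype matrix
#'
#' Matches scoring records to cohort variants by (chrom, pos), then
#' resolves allele orientation: if the effect allele is the cohort ALT the
#' dosage is used as-is (orientation +1); if it is the REF the dosage is
#' complemented (2 - dosage, orientation -1); if alleles agree only after
#' strand complementation the same rule is applied on the complemented
#' alleles. Scoring records with no positional or allelic match are
#' dropped and counted. Strand-ambiguous (A/T, C/G) records are kept and
#' matched positionally by default — appropriate when scoring files and
#' genotypes share a genome build, as with sequencing data — or dropped
#' when `drop_ambiguous = TRUE`.
#'
#' @param scoring A `scoring_file`.
#' @param geno A `genotype_matrix`.
#' @param drop_ambiguous Drop strand-ambiguous scoring records?
#' @return An object of class `prs_harmonized`: `variant_index` (columns of
#'   the dosage matrix), `weight`, `orientation` (+1/-1), `strand_flipped`
#'   (logical), `n_matched`, `n_unmatched`, `n_ambiguous_dropped`, `pgs_id`.
#' @export
harmonize <- function(scoring, geno, drop_ambiguous = FALSE) {
  v <- geno$variants
  geno_key <- paste(v$chrom, v$pos)
  sc_key <- paste(scoring$chrom, scoring$pos)
  hit <- match(sc_key, geno_key)

  n <- nrow(scoring)
  orientation <- rep(NA_real_, n)
  flipped <- rep(FALSE, n)
  ambiguous <- is_ambiguous_pair(scoring$effect_allele, scoring$other_allele)
  n_amb_dropped <- 0L
  if (drop_ambiguous && any(ambiguous)) {
    n_amb_dropped <- sum(ambiguous & !is.na(hit))
    hit[ambiguous] <- NA_integer_
  }

  idx <- which(!is.na(hit))
  for (i in idx) {
    j <- hit[i]
    ea <- scoring$effect_allele[i]
    oa <- scoring$other_allele[i]
    ok_other <- function(x) is.na(oa) || oa == "" || oa == x
    if (ea == v$alt[j] && ok_other(v$ref[j])) {
      orientation[i] <- 1
    } else if (ea == v$ref[j] && ok_other(v$alt[j])) {
      orientation[i] <- -1
    } else {
      cea <- comp_allele(ea)
      coa <- if (is.na(oa) || oa == "") oa else comp_allele(oa)
      ok_cother <- function(x) is.na(coa) || coa == "" || coa == x
      if (cea == v$alt[j] && ok_cother(v$ref[j])) {
        orientation[i] <- 1; flipped[i] <- TRUE
      } else if (cea == v$ref[j] && ok_cother(v$alt[j])) {
        orientation[i] <- -1; flipped[i] <- TRUE
      }
    }
  }

  keep <- which(!is.na(orientation))
  if (!length(keep))
    stop("harmonize: zero scoring records matched the genotype matrix")
  structure(list(
    variant_index = hit[keep],
    weight = scoring$weight[keep],
    orientation = orientation[keep],
    strand_flipped = flipped[keep],
    n_matched = length(keep),
    n_unmatched = n - length(keep) - n_amb_dropped,
    n_ambiguous_dropped = n_amb_dropped,
    pgs_id = attr(scoring, "pgs_id")
  ), class = "prs_harmonized")
}

#' @export
print.prs_harmonized <- function(x, ...) {
  cat("prs_harmonized [", x$pgs_id, "]: ", x$n_matched, " matched (",
      sum(x$strand_flipped), " strand-flipped), ", x$n_unmatched,
      " unmatched, ", x$n_ambiguous_dropped, " ambiguous dropped\n", sep = "")
  invisible(x)
}
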