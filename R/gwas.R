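#' Genomic inflation factor lambda
#'
#' Median of the 1-df chi-square statistics implied by the p-values,
#' divided by the null median 0.4549364 (qchisq(0.5, 1)). Lambda near 1
#' indicates well-calibrated association tests.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Scalar lambda.
#' @export
genomic_lambda <- function(pvalues) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (!length(pvalues)) stop("genomic_lambda: empty p-value vector")
  if (any(pvalues <= 0 | pvalues > 1)) stop("p-values must be in (0, 1]")
  chi <- stats::qchisq(pvalues, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Greedy distance-based clumping of association results
#'
#' Restricts to variants with p below `p_threshold`, then repeatedly
#' takes the lowest-p unassigned variant as a locus lead and absorbs all
#' unassigned variants on the same chromosome within `window_bp` of it.
#' Distance-only clumping (no LD pruning): the window plays the role of
#' the locus definition used for replication.
#'
#' @param stats A `summary_stats` data.frame (needs `chrom`, `pos`, `p`,
#'   optionally `rsid`).
#' @param p_threshold Inclusion threshold (default 1e-4).
#' @param window_bp Half-window around the lead (default 300000).
#' @return A `clumped_loci` data.frame, one row per locus: `locus`,
#'   `chrom`, `pos`, `rsid`, `p` (the lead), `n_members`, `span_lo`,
#'   `span_hi`; attribute `members` lists the row indices of `stats` in
#'   each locus (lead first).
#' @export
clump <- function(stats, p_threshold = 1e-4, window_bp = 300000) {
  cand <- which(stats$p < p_threshold)
  # deterministic: by p, ties by chrom then position
  cand <- cand[order(stats$p[cand], stats$chrom[cand], stats$pos[cand])]
  assigned <- rep(FALSE, length(cand))
  loci <- list(); members <- list()
  while (any(!assigned)) {
    lead_i <- which(!assigned)[1]
    lead <- cand[lead_i]
    in_win <- !assigned &
      stats$chrom[cand] == stats$chrom[lead] &
      abs(stats$pos[cand] - stats$pos[lead]) <= window_bp
    mem <- cand[in_win]
    mem <- c(lead, setdiff(mem, lead))
    assigned[in_win] <- TRUE
    members[[length(members) + 1L]] <- mem
    loci[[length(loci) + 1L]] <- data.frame(
      chrom = stats$chrom[lead], pos = stats$pos[lead],
      rsid = if (!is.null(stats$rsid)) stats$rsid[lead] else NA_character_,
      p = stats$p[lead], n_members = length(mem),
      span_lo = min(stats$pos[mem]), span_hi = max(stats$pos[mem]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, loci)
  if (is.null(out)) out <- data.frame(chrom = character(), pos = integer(),
                                      rsid = character(), p = numeric(),
                                      n_members = integer(),
                                      span_lo = integer(), span_hi = integer())
  out <- cbind(locus = seq_len(nrow(out)), out)
  attr(out, "members") <- members
  class(out) <- c("clumped_loci", "data.frame")
  out
}

#' Locus-level replication against a known-loci catalog
#'
#' A lead variant replicates a catalog entry when both lie on the same
#' chromosome within `window_bp` of each other. Replicated catalog loci
#' are counted once per distinct locus label, regardless of how many
#' catalog SNVs or leads fall in the window.
#'
#' @param leads data.frame of lead variants (`chrom`, `pos`, and ideally
#'   `rsid`, `p`), e.g. a `clumped_loci` table.
#' @param catalog A `known_loci` catalog.
#' @param window_bp Matching window (default 300000).
#' @return List with `matched` (leads that hit the catalog, with the
#'   nearest catalog locus label), `unmatched` (the rest),
#'   `replicated_loci` (distinct catalog locus labels hit),
#'   `n_replicated`, `n_catalog_loci`.
#' @export
replicate_loci <- function(leads, catalog, window_bp = 300000) {
  hit_locus <- rep(NA_character_, nrow(leads))
  hit_dist <- rep(NA_real_, nrow(leads))
  for (i in seq_len(nrow(leads))) {
    same <- catalog$chrom == leads$chrom[i]
    if (!any(same)) next
    d <- abs(catalog$pos[same] - leads$pos[i])
    j <- which.min(d)
    if (d[j] <= window_bp) {
      hit_locus[i] <- catalog$locus[same][j]
      hit_dist[i] <- d[j]
    }
  }
  matched <- cbind(leads[!is.na(hit_locus), , drop = FALSE],
                   catalog_locus = hit_locus[!is.na(hit_locus)],
                   distance = hit_dist[!is.na(hit_locus)])
  replicated <- character(0)
  for (i in seq_len(nrow(catalog))) {
    same <- leads$chrom == catalog$chrom[i]
    if (any(same) && any(abs(leads$pos[same] - catalog$pos[i]) <= window_bp))
      replicated <- c(replicated, catalog$locus[i])
  }
  replicated <- unique(replicated)
  list(matched = matched,
       unmatched = leads[is.na(hit_locus), , drop = FALSE],
       replicated_loci = replicated,
       n_replicated = length(replicated),
       n_catalog_loci = length(unique(catalog$locus)))
}

#' Exact-match replication of previously reported SNVs
#'
#' Intersects the association results with the catalog by (chrom, pos)
#' (falling back to rsid when positions are absent), applies the
#' Bonferroni threshold alpha / n_overlap, and also reports the subset
#' below a secondary nominal cutoff.
#'
#' @param stats A `summary_stats` data.frame.
#' @param catalog A `known_loci` catalog.
#' @param alpha Family-wise error rate (default 0.05).
#' @param secondary_p Nominal secondary cutoff (default 0.01).
#' @return List with `n_overlap`, `bonferroni_threshold`, `significant`
#'   (rows of `stats` below the Bonferroni threshold), `nominal` (rows
#'   below `secondary_p`).
#' @export
exact_match_replication <- function(stats, catalog, alpha = 0.05,
                                    secondary_p = 0.01) {
  key_s <- paste(stats$chrom, stats$pos)
  key_c <- paste(catalog$chrom, catalog$pos)
  ov <- key_s %in% key_c
  if (!is.null(stats$rsid))
    ov <- ov | (!is.na(stats$rsid) & stats$rsid %in% catalog$rsid)
  if (!any(ov)) stop("no overlap between association results and catalog")
  sub <- stats[ov, , drop = FALSE]
  thr <- alpha / nrow(sub)
  list(n_overlap = nrow(sub), bonferroni_threshold = thr,
       significant = sub[sub$p < thr, , drop = FALSE],
       nominal = sub[sub$p < secondary_p, , drop = FALSE])
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools per-variant effects across studies with weights 1/SE^2:
#' pooled beta = sum(w b)/sum(w), pooled SE = 1/sqrt(sum(w)), p from the
#' two-sided normal. Effect alleles are harmonized to the first study
#' carrying each variant: a study whose effect/other alleles are swapped
#' relative to that orientation has its beta sign (and EAF) flipped;
#' strand-complement matches are accepted; any other allele mismatch is
#' an error. Heterogeneity is flagged (not tested) when the 95% CIs of
#' the two extreme study betas fail to overlap.
#'
#' @param studies List of `summary_stats` data.frames.
#' @return A `meta_result` data.frame: `chrom`, `pos`, `rsid`, `ea`,
#'   `nea`, `beta`, `se`, `p`, `n_studies`, `het_flag`; attribute
#'   `per_study` holds the harmonized per-study betas/SEs.
#' @export
meta_fixed <- function(studies) {
  stopifnot(length(studies) >= 1)
  for (s in studies) if (any(s$se <= 0)) stop("meta_fixed: SE <= 0 in input")
  key <- function(s) paste(s$chrom, s$pos)
  ref <- list()   # first-seen orientation per variant
  for (s in studies) {
    k <- key(s)
    new <- !(k %in% names(ref))
    for (i in which(new)) ref[[k[i]]] <- s[i, c("chrom", "pos", "rsid", "ea", "nea")]
  }
  rows <- list(); per_study <- list()
  for (k in names(ref)) {
    r <- ref[[k]]
    bs <- c(); ses <- c()
    for (si in seq_along(studies)) {
      s <- studies[[si]]
      i <- which(key(s) == k)
      if (!length(i)) next
      i <- i[1]
      o <- allele_orientation(s$ea[i], s$nea[i], r$ea, r$nea)
      if (is.na(o))
        stop("meta_fixed: irreconcilable alleles at ", k, " (",
             s$ea[i], "/", s$nea[i], " vs ", r$ea, "/", r$nea, ")")
      bs <- c(bs, o * s$beta[i]); ses <- c(ses, s$se[i])
    }
    w <- 1 / ses^2
    b <- sum(w * bs) / sum(w)
    se <- 1 / sqrt(sum(w))
    # min/max flag: extreme study CIs fail to overlap
    hi <- which.max(bs); lo <- which.min(bs)
    het <- length(bs) > 1 &&
      (bs[hi] - bs[lo]) > 1.959964 * (ses[hi] + ses[lo])
    rows[[k]] <- data.frame(chrom = r$chrom, pos = r$pos, rsid = r$rsid,
                            ea = r$ea, nea = r$nea, beta = b, se = se,
                            p = 2 * stats::pnorm(-abs(b / se)),
                            n_studies = length(bs), het_flag = het,
                            stringsAsFactors = FALSE)
    per_study[[k]] <- data.frame(beta = bs, se = ses)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_study") <- per_study
  class(out) <- c("meta_result", "data.frame")
  out
}

# +1 if (ea, nea) matches the reference orientation (directly or by
# strand complement), -1 if swapped, NA if irreconcilable. Ambiguous
# (A/T, C/G) pairs are matched directly first, so they resolve to +1
# or -1 by position, never by strand guesswork.
allele_orientation <- function(ea, nea, ref_ea, ref_nea) {
  if (ea == ref_ea && nea == ref_nea) return(1)
  if (ea == ref_nea && nea == ref_ea) return(-1)
  cea <- comp_allele(ea); cnea <- comp_allele(nea)
  if (cea == ref_ea && cnea == ref_nea) return(1)
  if (cea == ref_nea && cnea == ref_ea) return(-1)
  NA_real_
}
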