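---
title: "Methods: PRS validation and case-control genetics with prscohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS validation and case-control genetics with prscohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

prscohort implements the analysis stages of a polygenic risk score (PRS)
validation study in a sequenced case-control cohort: published scoring
files are applied to cohort genotypes, the resulting scores are evaluated
for association and discrimination, single-variant results are compared
against known disease loci, rare variants are collapsed into gene-level
burden statistics, and a multi-SNV haplotype is tested for case-control
frequency differences. Because the genotype data such studies use are
access-controlled, the package ships a synthetic cohort generator that
reproduces the statistical structure every stage assumes, so the whole
pipeline is exercisable and testable from code alone.

```{r setup}
library(prscohort)
```

## Scoring and harmonization

A PRS is a weighted sum of effect-allele dosages,
$s_j = \sum_i w_i d_{ij}$, with weights from a published scoring file.
Before scoring, each scoring record is matched to a cohort variant by
chromosome and position; orientation is resolved by allele comparison.
If the effect allele equals the cohort ALT allele the dosage is used
directly; if it equals REF the dosage is complemented ($2-d$); if the
alleles agree only after strand complementation, the same rule applies
to the complemented alleles. Records matching no cohort variant are
dropped and counted — sequencing call sets are keyed positionally on a
single build, so no liftover or imputation is attempted. Strand-ambiguous
pairs (A/T, C/G) are kept and matched positionally by default, the
appropriate choice when scores and genotypes share a genome build;
`drop_ambiguous = TRUE` discards them for array-style inputs of uncertain
strand.

Missing dosages are imputed at scoring time with twice the cohort
effect-allele frequency (the mean oriented dosage), the standard practice
that keeps a sample's score unbiased under missingness at random;
`"zero"` and `"strict"` policies are available. A sample missing at every
matched variant gets a missing score rather than a silently hollow one.

Scores are standardized to z-scores with the $n-1$ denominator, either
over the whole cohort or within each ancestry stratum
(`scope = "per_ancestry"`). Within-ancestry centering and scaling removes
the mean shift between ancestry groups that would otherwise masquerade
as risk differences when a single score is applied across a
multi-ancestry cohort.

### The ensemble score

`ensemble_prs()` combines several standardized component PRSs. The
default is the unweighted mean of the component z-scores,
re-standardized — the minimal construction that pools components carrying
partly orthogonal information, and our default because it needs no
training data and cannot overfit. A `"stacked"` mode learns a logistic
combination by stratified 5-fold cross-validation (seed 42 by default),
assigning each sample its out-of-fold linear predictor; it can dominate
the mean when components differ greatly in strength, at the cost of
extra variance. Both are exposed because ensemble definitions vary
across studies; neither is claimed to replicate any particular published
ensemble exactly. Weak components are never dropped automatically —
discarding an underperforming score is an analyst decision.

## Association and discrimination

`or_per_sd()` fits a covariate-adjusted logistic model
$\mathrm{logit}\,P(\text{case}) = \beta_0 + \beta z + \gamma'c$ and
reports $e^{\beta}$ — the odds ratio per standard deviation of the score
(OR~1SD~) — with Wald 95% CI. Fits go through iteratively reweighted
least squares (tolerance $10^{-8}$, 100 iterations) with rank and
separation diagnostics. The usual covariate set is age, sex, BMI and
genotype principal components, each optional. Note the non-collapsibility
of the logistic model: when strong covariates (e.g. a 19-year mean age
gap between cases and controls) belong to the generating model, the
unadjusted marginal OR per SD is attenuated relative to the conditional
one, which is why parameter-recovery checks in the test-suite adjust for
the generating covariates.

Discrimination is summarized by the AUC, computed as the Mann-Whitney
probability that a random case outscores a random control (ties counted
half), with DeLong's variance from the empirical structural components
and a normal CI truncated to $[0,1]$. `delong_paired_test()` compares two
correlated AUCs measured on the same samples through the covariance of
their structural components; two identical score vectors give $z=0$,
$p=1$ by convention rather than an error. AUCs from models that include
age and sex are expected to exceed the PRS-only AUC whenever those
covariates associate with status — an inflation, not an improvement of
the genetic signal, which is why `match_controls()` (greedy 1:ratio
nearest-age matching within exact sex strata, each control used once) is
provided to rebuild a covariate-balanced sub-cohort.

`decile_analysis()` bins samples into ten equal-count groups of
increasing z (ties broken by stable input order, so group sizes differ by
at most one — the binning of tied scores is otherwise arbitrary) and
contrasts the top decile against all remaining samples (OR~vsAll~) and
against the bottom decile (OR~vsLowest~). The headline estimates are
crude 2×2 Woolf odds ratios with the Haldane-Anscombe 0.5 correction
applied — and flagged — only when a cell is empty; covariate-adjusted
logistic versions are emitted alongside when covariates are given, since
studies differ in which they report. OR~vsLowest~ exceeds OR~vsAll~ for
any risk-increasing score, because the reference group excludes the
middle of the distribution.

## Post-GWAS machinery

Per-variant association is `fit_logistic()` applied variant by variant;
the package adds what comes after. `genomic_lambda()` is the median
association chi-square over its null median (0.4549364).
`clump()` groups variants below a p threshold into loci greedily: the
lowest-p unassigned variant leads a locus and absorbs everything
unassigned within the window on its chromosome. Clumping is
distance-only; the window defaults to 300 kb, matching the replication
window, since the LD parameters behind published locus counts are rarely
stated and an LD-aware clump requires a reference panel out of scope
here. `replicate_loci()` calls a lead replicated when it lies within
300 kb of a catalog SNV, counting each catalog locus label once;
`exact_match_replication()` intersects results with the catalog by
position and applies the Bonferroni threshold $\alpha/n_{\text{overlap}}$
plus a nominal 0.01 cutoff. `meta_fixed()` pools per-variant effects by
inverse variance ($w_k = 1/\mathrm{SE}_k^2$), flipping a study's beta
when its effect allele is swapped relative to the first-seen orientation
and erroring on irreconcilable alleles; heterogeneity is flagged — not
tested — when the extreme studies' CIs fail to overlap.

## Rare-variant burden

The case-control ratio (CCR) of a variant is its effect-allele frequency
in cases over controls, deliberately not minor-allele-folded so the
direction of enrichment survives. Two substitution rules handle zeros: a
variant absent from controls gets the lowest nonzero control MAF as
denominator — in a sequenced cohort, a control singleton,
$1/(2n_{\text{controls}})$ — yielding a flagged pseudo-CCR; a variant
absent from cases is ignored. With 1014 cases and 6009 controls a case
doubleton against the control-singleton denominator gives
$(2/2028)/(1/12018) = 11.85$, and 3 or 4 case alleles give 17.79 and
23.70 — the pseudo-CCR family those inputs imply. Gene-level CCR is
reported both as the ratio of summed allele counts (the default
headline, robust when per-variant counts are tiny) and as the ratio of
mean per-variant MAFs.

A carrier holds at least one alternate allele at any qualifying variant
of a gene (qualifying = impact class or ClinVar class in the filter,
cohort frequency below `maf_max`, default 0.01 — "rare" is a convention,
so it is configurable). `carrier_or()` gives the carrier 2×2 odds ratio
with Woolf CI; `collapse_test()` is the two-sided Fisher exact test on
that table. `vc_score_test()` is the variance-component (SKAT-style)
score test $Q=\sum_j w_j^2 (g_j'(y-\hat\mu_0))^2$ with null fitted values
from the covariate logistic model and default Beta(1, 25) MAF weights;
its null distribution, a weighted sum of 1-df chi-squares, is
approximated by Liu's moment-matched noncentral chi-square. The
approximation is accurate at conventional levels but can understate
extreme tail significance; it is flagged approximate, and with a single
variant it collapses exactly to the 1-df score test.

## Haplotype analysis

`em_haplotype_freq()` estimates haplotype frequencies over up to 10 SNVs
from unphased genotypes by EM under within-group Hardy-Weinberg
equilibrium: each sample's compatible diplotypes get posterior weights
proportional to the product of current haplotype frequencies, and
frequencies are re-estimated from expected counts. Initialization is
uniform over haplotypes compatible with at least one sample, with
lexicographic order breaking any ties, so runs are deterministic; the
log-likelihood trace is stored and is non-decreasing by construction.
Missing genotypes expand the compatible-diplotype set (they are
marginalized, not dropped). Convergence is the largest frequency change
falling below $10^{-8}$ within 1000 iterations; non-convergence warns
with the iteration count rather than failing, since a long flat ridge
still yields usable frequencies. When phase is unambiguous (no sample
doubly heterozygous), EM reproduces direct haplotype counting exactly.

`haplotype_cc_test()` estimates frequencies separately in cases,
controls and the pooled sample, then tests the target haplotype by
logistic regression of status on each sample's posterior expected count
of that haplotype under the pooled frequencies — a score-type dosage
test that never requires phase certainty, optionally covariate-adjusted.
Only the target-haplotype test is provided; omnibus all-haplotype tests
are out of scope.

## Case-control power

`cc_power()` is the analytic power of the per-allele (log-additive)
test: control frequency $p_0$ and odds ratio OR give case frequency
$p_1 = p_0\,\mathrm{OR}/(1+p_0(\mathrm{OR}-1))$, and the two-proportion
z statistic on allele counts yields two-sided power
$\Phi(z-z_{1-\alpha/2})+\Phi(-z-z_{1-\alpha/2})$, which equals $\alpha$
exactly at OR = 1. For a 1014-case / 6009-control design at OR 1.2 and
MAF 0.4 this gives 0.96 at $\alpha=0.05$ and 0.88 at $\alpha=0.01$,
matching dedicated power software to two decimals without its full
likelihood machinery. `cc_power_sim()` is the Monte-Carlo cross-check.

## The synthetic cohort generator

`sim_cohort()` produces everything the pipeline consumes, as a pure
function of a configuration and a seed.

* **Structure.** Common genotypes follow the Balding-Nichols model:
  ancestral frequency $p \sim U(0.05, 0.95)$ per variant, per-ancestry
  frequency $\sim \mathrm{Beta}(p(1-F_{st})/F_{st},
  (1-p)(1-F_{st})/F_{st})$, genotypes Binomial(2, freq) within stratum.
  It is the simplest model with a single differentiation knob; default
  three strata with proportions 0.50/0.35/0.15 and $F_{st}=0.05$, a
  realistic magnitude for continental-scale heterogeneity in an admixed
  regional cohort.
* **Liability.** True weights $\sim N(0, 1/m)$; the standardized
  weighted dosage sum is the true PRS; case probability is
  logistic in the PRS (default OR per SD 1.8), centered age (0.1 per
  year) and male sex (1.1 log odds), with the intercept tuned by
  bisection so the expected case fraction matches the configured one
  within 0.5%. The age/sex defaults recreate the covariate imbalance of
  cardiac case-control studies — simulated cases come out older and more
  often male. Principal components are computed from the simulated
  genotypes themselves.
* **Rare burden.** Per gene, samples become carriers at their group's
  configured rate (defaults chosen so the four default lipid genes show
  case/control carrier-rate ratios between about 2 and 6); one
  moderate-impact variant carried by a single control is planted so the
  pseudo-CCR denominator exists by construction.
* **Haplotypes.** Each sample draws two haplotypes i.i.d. from its
  group's pool and phase is discarded. The default pool is a four-
  haplotype, 7-SNV block whose first haplotype is protective: frequency
  0.17 in cases versus 0.213 in controls.

Default size is 145 cases / 860 controls — one seventh of the motivating
cohort, keeping the case fraction and the test suite fast —
with `full_scale = TRUE` switching to 1014 / 6009. The generator omits
linkage disequilibrium between common variants, recombination within the
haplotype block, genotype missingness patterns of real pipelines, and
relatedness; passing tests therefore demonstrate correctness of the
statistical machinery under the stated models, not robustness to every
artifact of production sequencing data.

## Numerical conventions

Variant identity is (chrom, pos, ref, alt) with 1-based positions; rsIDs
are advisory. Logistic fits: IRLS tolerance $10^{-8}$, 100 iterations,
error on rank deficiency or perfect separation. 2×2 odds ratios: Woolf
log-SE, Haldane-Anscombe only on empty cells, always flagged. Decile
ties: stable input order. EM ties: lexicographic. All randomized
procedures (stacking folds, simulators) take explicit seeds and restore
the caller's RNG state. Test-suite problem sizes — e.g. 100 replicates
at full cohort scale for OR recovery, 1000 null replicates at n = 300
for the paired DeLong size check, n = 5000 for haplotype-frequency
recovery — were chosen as the smallest sizes at which the Monte-Carlo
error of each check is comfortably below the property being asserted.

## Known limitations

No liftover, no multiallelic normalization, no LD-aware clumping, no
heterogeneity statistics beyond the CI-overlap flag, no Davies exact
tail for the variance-component test, no omnibus haplotype test, and no
PRS training: scoring files are always inputs. These boundaries mirror
what the analysis stages themselves need; the surrounding production
steps (variant calling, ancestry inference, annotation) are upstream of
this package.
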