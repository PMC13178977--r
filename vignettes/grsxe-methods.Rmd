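---
title: "Methods: models, simulation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistics it implements, the
synthetic cohorts it tests them on, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The analysis model

The package targets a frequency-matched case-control design: cases with the
outcome (here, childhood obesity) and controls matched on the marginal/joint
distribution of sex, age band and school. Every adjusted estimate comes from
a multivariate logistic regression of case status on the term of interest
plus the standard adjustment set — age group, sex, maternal and paternal
education, and household income — all entered as categorical indicators with
the first observed level as reference. Under case-control sampling the
logistic slope coefficients remain consistent for the population log odds
ratios (only the intercept absorbs the sampling fractions), which is what
justifies both the analysis and the way the generator builds cohorts
(prospective disease model, then case-control sampling).

Stages, in pipeline order:

1. **QC** (`qc_report`): per-variant genotype counts by status, minor-allele
   frequency, call rate; Hardy–Weinberg goodness of fit in controls only
   (cases are expected to depart from HWE at truly associated loci, so they
   are reported descriptively). The chi-square uses expected counts
   $np^2, 2npq, nq^2$ at the observed allele frequency, no continuity
   correction, 1 df. The permutation correction pools the $2n$ observed
   alleles and re-pairs them at random into $n$ genotypes — the permutation
   analogue of the exact test, conditional on allele counts — and reports
   $(1 + \#\{\chi^2_b \ge \chi^2_{obs}\})/(B+1)$.
2. **Single-locus association** (`association_scan`): genotypic, dominant,
   recessive and additive codings of the risk-oriented dosage; crude ORs by
   the closed 2×2 form with Woolf intervals; adjusted ORs by the package's
   IRLS fitter; permutation p per contrast by unrestricted relabelling of
   case/control status with the design fixed, using |Wald z| as the permuted
   statistic.
3. **CART screening** (`grow_tree` and friends): binary recursive
   partitioning over genotype categories, Gini impurity
   $1 - p^2 - (1-p)^2$, exhaustive enumeration of left-branch category
   subsets (at most 3 per biallelic variant up to complement symmetry),
   node-size constraints (minimum 100 to split, minimum 50 per child),
   stratified 10-fold cross-validation for predictive accuracy, and adjusted
   ORs of terminal nodes against the lowest-risk node.
4. **GRS** (`compute_grs`, `categorize_grs`, `grs_association`,
   `stratified_grs`): unweighted (risk-allele count) and weighted
   (β-weighted count) scores over the "important" variants; quartile
   low/medium/high bins; trend, per-allele, high-vs-rest, and stratified
   contrasts with Z-test heterogeneity.
5. **Interaction** (`crossover_table`, `bootstrap_interaction`): the 2×2
   crossover design with joint reference, RERI/AP/IOR closed forms, and
   percentile bootstrap CIs stratified by status.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `B` permutations (HWE and association) | 1000 | resolution 1/1001 ≈ 0.001, adequate for α = 0.05 decisions at modest cost |
| `B` bootstrap (interaction CIs) | 1000 | standard percentile-CI practice; tails estimated from 25 draws per side |
| CART `min_parent` / `min_child` | 100 / 50 samples | prevents unstable small-node splits at cohort sizes in the low thousands |
| IRLS `tol` / `max_iter` | 1e-8 / 100 | coefficient and score convergence well below reporting precision |
| separation threshold | \|β\| > 15 | odds ratios beyond e^15 are numerically meaningless; the fit is flagged, not repaired |
| GRS cutpoints | Q1/Q3, inverse-ECDF | see "Quartile snapping" below |
| CI level | 95% two-sided | field convention |

## The synthetic cohort generator

`sim_config()` defaults describe the study-like condition the package is
tested under: 1123 cases / 1231 controls; twelve biallelic variants of which
four carry per-risk-allele log-odds 0.268, 0.217, 0.110 and 0.044 (the
additive-model coefficients that define the published weighted score) and
eight are null; covariate margins matching the study's descriptive table
(68% boys; age bands 19/49/32%; school derived from age band); inadequate
physical activity prevalence 0.86 and inadequate sleep 0.80, each with a
mild log-odds effect of 0.15 on disease.

Choices the source material does not fix, made once and kept:

* **Risk-allele frequencies 0.20 / 0.17 / 0.21 / 0.22.** Allele frequencies
  of the four score variants are not restated in the material available to
  the package; these values are plausible for a southern-Han population and
  make the probability of carrying zero risk alleles ≈ 0.17, matching the
  published low-GRS bin (~18% of the sample). One effect variant
  (rs6713532) has its risk allele on the REF strand so the orientation path
  is exercised end to end.
* **Baseline log-odds −2.25**, giving a marginal prevalence near 0.15 under
  the default effects — a realistic childhood-obesity figure and enough case
  yield from moderate pools.
* **Control:case ratio ~1.1:1**, the observed ratio.
* **Missingness** ~1.3–1.5% on the lifestyle fields and 0.1% per genotype,
  matching the published table denominators and call rates (>99%).

The generator draws a *prospective* pool (genotypes under HWE at the
configured ALT frequency, optionally distorted by an inbreeding-style factor
`f` scaling heterozygosity by $1-f$; covariates independent of genotype, as
the study's descriptive table shows no case-control covariate differences),
assigns disease by the logistic model, then samples cases and
frequency-matched controls. Frequency matching uses largest-remainder
apportionment of control targets across matching cells with proportional
reallocation on shortfall.

What it deliberately does **not** emulate: linkage disequilibrium between
variants (the study pre-selected variants at r² < 0.8 and analyses them
independently), genotype–covariate confounding (available via a hook but off
by default), continuous BMI outcomes, and recall-type measurement error in
lifestyle reporting. Passing tests therefore demonstrate calibration and
correctness of the estimators under clean MCAR, LD-free conditions — not
robustness to confounded or differentially mismeasured real data.

## Numerical and procedural choices

* **IRLS, not `glm`.** The fitter is the package's own Newton/IRLS with Wald
  SEs from the inverse observed information; `stats::glm` serves as an
  independent cross-check in the tests (agreement to 1e-6 requires
  tightening `glm`'s deviance-based stopping rule to `epsilon = 1e-12`,
  since its default stops earlier than the package's score/step criterion).
* **Permutation scheme for HWE** re-pairs alleles (conditional on allele
  counts). Relabelling case/control status instead is a different null; the
  re-pairing scheme is the standard exact-test analogue and is exposed as
  the implementation's single scheme. It is validated in-suite against a
  brute-force allele-shuffle oracle.
* **Permutation scheme for association** permutes status labels
  unrestricted, per-test (not family-wise max-T): the published per-contrast
  permutation p-values track the asymptotic ones (e.g. 0.152 vs 0.160),
  which a max-T correction would not produce. The permuted statistic is
  |Wald z|. A subtlety the test suite documents: with a lone dosage
  covariate the logistic sufficient statistic collapses to the integer
  $\sum_i x_i y_i$, the permutation distribution becomes coarsely discrete,
  and the tie-inclusive p is conservative *by construction*; calibration is
  therefore assessed on the adjusted design, where the covariates refine the
  sufficient statistic.
* **Quartile snapping.** `categorize_grs` uses inverse-ECDF (type-1)
  quantiles with low = score < Q1 and high = score ≥ Q3. On integer scores
  the bins are unions of whole scores; this is the rule that reproduces
  published-style bins (low = {0}, medium = {1,2}, high = {3+}) on
  distributions like the study's. Quartiles are computed on the pooled
  case+control sample. Q1 = Q3 errors with advice to pass explicit
  cutpoints.
* **GRS completeness.** A sample missing any component variant carries no
  score and is excluded from GRS analyses (matching the published "missing
  for one case and three controls" accounting); it remains in single-locus
  analyses of the variants it does have.
* **CART determinism.** Ties in Gini decrease break by candidate order, then
  lexicographically smallest left subset; missing genotypes at a split
  follow the majority branch (no surrogate splits — missingness here is
  <1%). "Minimum 100 per parent" is read as 100 *samples* (standard CART
  usage; a `unit = "cases"` switch exists). No cost-complexity pruning:
  cross-validation is an accuracy evaluation, with stopping via node size
  and zero decrease.
* **Bootstrap.** Resamples are drawn with replacement within cases and
  within controls, preserving the design margins; percentile (not BCa)
  intervals; resamples with empty cells or non-converged fits are dropped
  and counted, with a warning above 10%. The adjusted model is refitted per
  resample (recombining crude cell ORs would ignore the covariates).
* **Zero cells** in crude 2×2 tables error by default; the
  Haldane–Anscombe +0.5 correction is opt-in.
* **Seeds.** One master seed fans out to per-stage seeds through a fixed
  integer derivation, so any stage can be rerun independently and the whole
  pipeline is bit-reproducible.

## Problem sizes in the test suite

Simulation-based checks run at sizes chosen to make their binomial/KS
acceptance bands informative: CI-coverage of the four configured per-allele
effects over 150 replicate cohorts of 2000+2000; permutation and HWE null
uniformity over 500 replicates (B = 199 permutations each); additive-null
bootstrap RERI coverage over 100 cohorts of 2000+2000 at B = 200; the
split-search oracle over dozens of instances of ≤200 samples × 3 variants.

## Known limitations

* Wald inference throughout; no profile-likelihood or exact logistic
  intervals, no Firth correction (separation is flagged only).
* The published *adjusted* ORs, CART topology and stratified estimates
  depend on individual-level data that is not available; the package
  reproduces their closed-form/worked-example quantities exactly and
  validates everything else by simulation calibration.
* The heterogeneity Z test assumes independent strata and normal
  coefficient estimates; with more than two strata the pairwise Z is
  against the first stratum, with Cochran's Q as the omnibus summary.
* `pairwise_r2` is composite (phase-free) LD on dosages, adequate for the
  r² < 0.8 screening use, not a haplotype-based estimate.
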