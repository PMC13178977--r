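# Per-variant quality control: genotype counts, Hardy-Weinberg goodness of
# fit with a permutation-corrected p-value, and pairwise composite LD.

#' Tally genotype counts from a dosage vector
#'
#' @param dosages Integer ALT (or risk) dosages in \{0, 1, 2, NA\}.
#' @return Named integer vector `n_AA`, `n_Aa`, `n_aa`, `n_missing` (AA =
#'   dosage 0).
#' @export
genotype_counts <- function(dosages) {
  dosages <- check_dosage(dosages)
  c(
    n_AA = sum(dosages == 0, na.rm = TRUE),
    n_Aa = sum(dosages == 1, na.rm = TRUE),
    n_aa = sum(dosages == 2, na.rm = TRUE),
    n_missing = sum(is.na(dosages))
  )
}

#' Hardy-Weinberg chi-square goodness of fit
#'
#' Expected counts are \eqn{np^2, 2npq, nq^2} from the observed allele
#' frequency; the statistic is \eqn{\sum (O-E)^2/E} with no continuity
#' correction, referred to chi-square with 1 df. Monomorphic variants cannot
#' be tested and are returned flagged with `tested = FALSE`.
#'
#' @param counts Named vector with `n_AA`, `n_Aa`, `n_aa` (as from
#'   [genotype_counts()]).
#' @return A one-row tibble: counts, `chi2`, `p_asymptotic`, `tested`.
#' @export
hwe_chi2 <- function(counts) {
  n_AA <- counts[["n_AA"]]; n_Aa <- counts[["n_Aa"]]; n_aa <- counts[["n_aa"]]
  n <- n_AA + n_Aa + n_aa
  if (n == 0) abort("no genotyped samples")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) {
    return(tibble(
      n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
      chi2 = NA_real_, p_asymptotic = NA_real_, tested = FALSE
    ))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  tibble(
    n_AA = n_AA, n_Aa = n_Aa, n_aa = n_aa,
    chi2 = chi2, p_asymptotic = pchisq(chi2, df = 1, lower.tail = FALSE),
    tested = TRUE
  )
}

# One HWE chi-square from genotype counts without tibble overhead (permutation
# inner loop).
hwe_stat <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
}

#' Permutation p-value for the HWE test
#'
#' The observed `2n` alleles are pooled and re-paired at random into `n`
#' genotypes `B` times (the permutation analogue of the exact test,
#' conditional on the allele counts); the p-value is
#' `(1 + #\{chi2_perm >= chi2_obs\}) / (B + 1)`. Re-pairing keeps allele
#' counts fixed, so the heterozygote count is drawn from its null
#' distribution; the result is invariant to allele relabelling.
#'
#' @param dosages Integer dosages in \{0, 1, 2, NA\}.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return The permutation p-value, or `NA` for a monomorphic variant.
#' @export
hwe_permutation_p <- function(dosages, B = 1000L, seed = 1L) {
  cts <- genotype_counts(dosages)
  n <- sum(cts[1:3])
  n_alt <- 2 * cts[["n_aa"]] + cts[["n_Aa"]]
  if (n == 0 || n_alt == 0 || n_alt == 2 * n) return(NA_real_)
  obs <- hwe_stat(cts[["n_AA"]], cts[["n_Aa"]], cts[["n_aa"]])
  withr_seed(seed, {
    hits <- 0L
    for (b in seq_len(B)) {
      # random pairing of the allele pool: the number of ALT alleles landing
      # in the first slot of each genotype vs the second is hypergeometric
      first <- stats::rhyper(1, n_alt, 2 * n - n_alt, n)
      second <- n_alt - first
      # heterozygotes arise where exactly one slot carries ALT; count by
      # drawing the overlap of the two slot-assignments
      hom_alt <- stats::rhyper(1, first, n - first, second)
      het <- first + second - 2 * hom_alt
      n_aa_b <- hom_alt
      n_AA_b <- n - het - hom_alt
      if (hwe_stat(n_AA_b, het, n_aa_b) >= obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (B + 1)
  })
}

#' Composite pairwise LD between two variants
#'
#' Squared Pearson correlation of the dosage vectors over complete pairs
#' (phase-free composite r-squared).
#'
#' @param dosages_a,dosages_b Integer dosage vectors of equal length.
#' @return r-squared in `[0,1]`, or `NA` (with a warning) if either variant is
#'   monomorphic among complete pairs.
#' @export
pairwise_r2 <- function(dosages_a, dosages_b) {
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) abort("need at least 2 complete pairs")
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warn("monomorphic variant among complete pairs; r2 undefined")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Per-variant QC report
#'
#' Genotype counts in cases and controls, minor-allele frequency, call rate,
#' and the HWE asymptotic and permutation p-values computed in controls only
#' (cases are reported descriptively).
#'
#' @param cohort Cohort tibble with `status` and dosage columns.
#' @param variants Variant tibble (or character vector of dosage column
#'   names).
#' @param B Permutations for the HWE correction.
#' @param seed Integer seed.
#' @return A tibble, one row per variant.
#' @export
qc_report <- function(cohort, variants, B = 1000L, seed = 1L) {
  ids <- variant_cols(cohort, variants)
  controls <- dplyr::filter(cohort, .data$status == 0)
  cases <- dplyr::filter(cohort, .data$status == 1)
  purrr::map_dfr(seq_along(ids), function(i) {
    v <- ids[i]
    cc <- genotype_counts(cases[[v]])
    ct <- genotype_counts(controls[[v]])
    d_all <- cohort[[v]]
    f <- sum(d_all, na.rm = TRUE) / (2 * sum(!is.na(d_all)))
    hw <- hwe_chi2(ct)
    tibble(
      variant_id = v,
      n_AA_case = cc[["n_AA"]], n_Aa_case = cc[["n_Aa"]], n_aa_case = cc[["n_aa"]],
      n_AA_control = ct[["n_AA"]], n_Aa_control = ct[["n_Aa"]], n_aa_control = ct[["n_aa"]],
      maf = min(f, 1 - f),
      call_rate = mean(!is.na(d_all)),
      hwe_chi2 = hw$chi2,
      hwe_p = hw$p_asymptotic,
      hwe_p_permutation = if (hw$tested) {
        hwe_permutation_p(controls[[v]], B = B, seed = derive_seed(seed, v))
      } else NA_real_
    )
  })
}
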