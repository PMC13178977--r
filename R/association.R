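# Descriptive case-control comparisons, crude odds ratios, and genotype
# codings for the single-locus models.

#' Pearson chi-square test on a contingency table
#'
#' \eqn{\sum (O-E)^2/E} with no continuity correction;
#' df = (r-1)(c-1).
#'
#' @param counts Matrix of non-negative counts (r x c).
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    abort("table has a zero margin")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p.value = unname(ct$p.value)
  )
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance t-test; Welch's unequal-variance form is available
#' via `welch = TRUE`.
#'
#' @param values_case,values_control Numeric vectors (n >= 2 each).
#' @param welch Use the Welch correction instead of pooled variance.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
two_sample_t <- function(values_case, values_control, welch = FALSE) {
  values_case <- values_case[!is.na(values_case)]
  values_control <- values_control[!is.na(values_control)]
  if (length(values_case) < 2 || length(values_control) < 2) {
    abort("both groups need at least 2 observations")
  }
  if (stats::var(values_case) == 0 && stats::var(values_control) == 0) {
    abort("zero pooled variance")
  }
  tt <- stats::t.test(values_case, values_control, var.equal = !welch)
  tibble(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = unname(tt$p.value)
  )
}

#' Crude odds ratio from a 2x2 table with Woolf confidence interval
#'
#' Cells are `a` exposed cases, `b` unexposed cases, `c` exposed controls,
#' `d` unexposed controls: OR = ad/bc, CI =
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})}.
#'
#' @param a,b,c,d Cell counts.
#' @param alpha Two-sided CI level (default 95% CI).
#' @param haldane Add 0.5 to every cell when any cell is zero
#'   (Haldane-Anscombe); off by default, in which case a zero cell errors.
#' @return Tibble with `or`, `conf.low`, `conf.high`, `p.value` (Wald on the
#'   log scale).
#' @export
crude_or <- function(a, b, c, d, alpha = 0.05, haldane = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!haldane) abort("zero cell; enable haldane = TRUE for the 0.5 correction")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - alpha / 2)
  tibble(
    or = exp(lor),
    conf.low = exp(lor - z * se),
    conf.high = exp(lor + z * se),
    p.value = 2 * pnorm(-abs(lor / se))
  )
}

#' Genotype coding for single-locus models
#'
#' Maps a risk-oriented dosage to the design column(s) of the chosen genetic
#' model: `genotypic` gives heterozygote and homozygote indicator columns
#' against the non-carrier reference, `dominant` an any-risk-allele indicator,
#' `recessive` a two-risk-allele indicator, `additive` the numeric dosage.
#' Missing dosages propagate to `NA` rows (excluded from fits).
#'
#' @param dosage Integer risk-allele dosages in \{0, 1, 2, NA\}.
#' @param model One of `"genotypic"`, `"dominant"`, `"recessive"`,
#'   `"additive"`.
#' @return A numeric matrix with one column (or two for `genotypic`).
#' @export
code_genotype <- function(dosage,
                          model = c("genotypic", "dominant", "recessive", "additive")) {
  model <- match.arg(model)
  dosage <- check_dosage(dosage)
  switch(model,
    genotypic = cbind(het = as.numeric(dosage == 1),
                      hom = as.numeric(dosage == 2)),
    dominant  = cbind(dominant = as.numeric(dosage >= 1)),
    recessive = cbind(recessive = as.numeric(dosage == 2)),
    additive  = cbind(additive = as.numeric(dosage))
  )
}

#' Indicator matrix of adjustment covariates
#'
#' Builds the design columns for the standard adjustment set: every covariate
#' enters as categorical indicators with the first observed level as the
#' reference. Covariates absent from the cohort, or with fewer than two
#' observed levels, are silently dropped.
#'
#' @param cohort Cohort tibble.
#' @param covariates Covariate column names.
#' @return A numeric matrix with `nrow(cohort)` rows.
#' @export
covariate_matrix <- function(cohort,
                             covariates = c("age_group", "sex", "maternal_edu",
                                            "paternal_edu", "income")) {
  covariates <- intersect(covariates, names(cohort))
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0))
  }
  cols <- lapply(covariates, function(cv) {
    x <- cohort[[cv]]
    lev <- unique(x[!is.na(x)])
    if (length(lev) < 2) return(NULL)
    m <- vapply(lev[-1], function(l) as.numeric(x == l), numeric(length(x)))
    colnames(m) <- paste0(cv, "_", lev[-1])
    m
  })
  do.call(cbind, cols[!vapply(cols, is.null, logical(1))])
}

#' Single-locus association table
#'
#' For each variant, fits the adjusted logistic model under the requested
#' genetic codings (risk-oriented when `variants` carries a `risk_allele`) and
#' optionally attaches a label-permutation p-value per contrast.
#'
#' @param cohort Cohort tibble.
#' @param variants Variant tibble with `variant_id`, and `risk_allele`,
#'   `ref_allele`, `alt_allele` for orientation (ALT orientation is used when
#'   absent).
#' @param models Genetic codings to fit.
#' @param covariates Adjustment covariates (categorical indicators).
#' @param B Number of permutations for `p_permutation`; `0` skips them.
#' @param seed Integer seed for the permutations.
#' @return Tibble: one row per variant x model contrast, with adjusted OR, CI,
#'   p and (optionally) permutation p.
#' @export
association_scan <- function(cohort, variants,
                             models = c("genotypic", "dominant", "recessive", "additive"),
                             covariates = c("age_group", "sex", "maternal_edu",
                                            "paternal_edu", "income"),
                             B = 0L, seed = 1L) {
  ids <- variant_cols(cohort, variants)
  has_orient <- is.data.frame(variants) && all(c("risk_allele", "alt_allele") %in% names(variants))
  covm <- covariate_matrix(cohort, covariates)
  purrr::map_dfr(ids, function(v) {
    dosage <- cohort[[v]]
    if (has_orient) {
      vi <- variants[variants$variant_id == v, ]
      dosage <- orient_to_risk(dosage, vi)
    }
    purrr::map_dfr(models, function(m) {
      gm <- code_genotype(dosage, m)
      X <- cbind(gm, covm)
      keep <- stats::complete.cases(X) & !is.na(cohort$status)
      fit <- try(fit_logistic(X[keep, , drop = FALSE], cohort$status[keep]), silent = TRUE)
      if (inherits(fit, "try-error") || !fit$converged) {
        return(tibble(
          variant_id = v, model = m, term = colnames(gm),
          or = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
          p.value = NA_real_, p_permutation = NA_real_, n = sum(keep)
        ))
      }
      td <- tidy(fit) %>% dplyr::filter(.data$term %in% colnames(gm))
      pp <- rep(NA_real_, nrow(td))
      if (B > 0) {
        pp <- vapply(td$term, function(trm) {
          permutation_p_association(
            X[keep, , drop = FALSE], cohort$status[keep], term = trm,
            B = B, seed = derive_seed(seed, paste0(v, m, trm))
          )
        }, numeric(1))
      }
      tibble(
        variant_id = v, model = m, term = td$term,
        or = exp(td$estimate),
        conf.low = exp(td$estimate - qnorm(0.975) * td$std.error),
        conf.high = exp(td$estimate + qnorm(0.975) * td$std.error),
        p.value = td$p.value, p_permutation = pp, n = sum(keep)
      )
    })
  })
}
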