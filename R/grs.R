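# Genetic risk scores: risk-allele orientation, unweighted and weighted
# totals, quartile categorisation, and the associated trend, per-allele and
# stratified analyses.

#' Orient an ALT-dosage to the risk allele
#'
#' Dosages are stored ALT-oriented at I/O; this flips them (`2 - dosage`)
#' where the designated risk allele is the REF allele. Missing stays missing.
#'
#' @param dosage Integer ALT dosages in \{0, 1, 2, NA\}.
#' @param variant One-row variant tibble with `risk_allele`, `ref_allele`,
#'   `alt_allele`.
#' @return Integer risk-allele dosages.
#' @export
orient_to_risk <- function(dosage, variant) {
  dosage <- check_dosage(dosage)
  if (!variant$risk_allele %in% c(variant$ref_allele, variant$alt_allele)) {
    abort(sprintf("risk allele %s is neither REF nor ALT for %s",
                  variant$risk_allele, variant$variant_id))
  }
  if (variant$risk_allele == variant$alt_allele) dosage else 2L - dosage
}

#' Compute unweighted and weighted genetic risk scores
#'
#' Unweighted GRS is the sum of risk-allele counts over the component
#' variants; weighted GRS weights each count by its per-allele log-odds
#' coefficient. Samples missing any component variant are flagged incomplete
#' and carry no score.
#'
#' @param cohort Cohort tibble with ALT-dosage columns.
#' @param weights Tibble with `variant_id`, `risk_allele`, `beta`, plus
#'   `ref_allele`/`alt_allele` for orientation.
#' @return Tibble: `sample_id`, `status`, `unweighted`, `weighted`,
#'   `complete`.
#' @export
compute_grs <- function(cohort, weights) {
  ids <- intersect(weights$variant_id, names(cohort))
  if (length(ids) == 0) abort("no component variants present in cohort")
  stopifnot(all(weights$beta >= 0), all(is.finite(weights$beta)))
  risk <- vapply(ids, function(v) {
    orient_to_risk(cohort[[v]], weights[weights$variant_id == v, ])
  }, numeric(nrow(cohort)))
  risk <- matrix(risk, nrow = nrow(cohort),
                 dimnames = list(NULL, ids))
  complete <- !apply(is.na(risk), 1, any)
  betas <- weights$beta[match(ids, weights$variant_id)]
  tibble(
    sample_id = cohort$sample_id,
    status = cohort$status,
    unweighted = ifelse(complete, as.integer(rowSums(risk)), NA_integer_),
    weighted = ifelse(complete, drop(risk %*% betas), NA_real_),
    complete = complete
  )
}

#' Categorise scores into low / medium / high by quartiles
#'
#' Uses the first and third quartiles of the pooled score distribution
#' (inverse-ECDF quantiles, so boundaries always fall on realised score
#' values): low is `score < Q1`, high is `score >= Q3`, medium between. On
#' integer scores the categories are therefore unions of whole-score bins.
#' Explicit `cutpoints = c(q1, q3)` override the quartiles.
#'
#' @param scores Numeric scores (NAs allowed, passed through).
#' @param cutpoints Optional explicit `c(lower, upper)` boundaries.
#' @return Factor with levels `low`, `medium`, `high`; the realised
#'   boundaries and per-category score ranges are attached as attributes
#'   `"cutpoints"` and `"ranges"`.
#' @export
categorize_grs <- function(scores, cutpoints = NULL) {
  obs <- scores[!is.na(scores)]
  if (length(obs) < 4) abort("need at least 4 non-missing scores")
  if (is.null(cutpoints)) {
    q1 <- quantile(obs, 0.25, type = 1, names = FALSE)
    q3 <- quantile(obs, 0.75, type = 1, names = FALSE)
    if (q1 == q3) {
      abort("degenerate score distribution (Q1 == Q3); supply explicit cutpoints")
    }
  } else {
    q1 <- cutpoints[1]; q3 <- cutpoints[2]
  }
  cat <- dplyr::case_when(
    is.na(scores) ~ NA_character_,
    scores < q1 ~ "low",
    scores >= q3 ~ "high",
    TRUE ~ "medium"
  )
  out <- factor(cat, levels = c("low", "medium", "high"))
  attr(out, "cutpoints") <- c(q1 = q1, q3 = q3)
  rng <- function(lv) {
    s <- scores[!is.na(scores) & cat == lv]
    if (length(s) == 0) c(NA_real_, NA_real_) else range(s)
  }
  attr(out, "ranges") <- rbind(low = rng("low"), medium = rng("medium"),
                               high = rng("high"))
  out
}

#' GRS-obesity association under several contrasts
#'
#' Fits crude and covariate-adjusted logistic models for the requested
#' contrast of a categorised (or continuous) score: `"three_level"` (medium
#' and high vs low), `"high_vs_rest"` (high vs low/medium), or `"per_unit"`
#' (the score as a numeric term). The trend p-value comes from the adjusted
#' model with category coded 0/1/2.
#'
#' @param cohort Cohort tibble (same row order as `profiles`).
#' @param profiles Tibble from [compute_grs()].
#' @param score `"unweighted"` or `"weighted"`.
#' @param contrast Contrast to fit.
#' @param covariates Adjustment covariates.
#' @param cutpoints Optional explicit category boundaries.
#' @return Tibble of effect estimates (one row per non-reference term), with
#'   `p_trend` attached for categorical contrasts.
#' @export
grs_association <- function(cohort, profiles,
                            score = c("unweighted", "weighted"),
                            contrast = c("three_level", "high_vs_rest", "per_unit"),
                            covariates = c("age_group", "sex", "maternal_edu",
                                           "paternal_edu", "income"),
                            cutpoints = NULL) {
  score <- match.arg(score)
  contrast <- match.arg(contrast)
  stopifnot(nrow(cohort) == nrow(profiles))
  s <- profiles[[score]]
  covm <- covariate_matrix(cohort, covariates)
  y <- cohort$status

  if (contrast == "per_unit") {
    terms <- cbind(score = as.numeric(s))
  } else {
    cat <- categorize_grs(s, cutpoints = cutpoints)
    if (any(table(cat) == 0)) abort("empty GRS category")
    if (contrast == "three_level") {
      terms <- cbind(medium = as.numeric(cat == "medium"),
                     high = as.numeric(cat == "high"))
    } else {
      terms <- cbind(high = as.numeric(cat == "high"))
    }
  }
  keep <- stats::complete.cases(terms) &
    (ncol(covm) == 0 | stats::complete.cases(covm))
  res <- purrr::map_dfr(colnames(terms), function(trm) {
    crude <- fit_logistic(terms[keep, trm, drop = FALSE], y[keep])
    adj <- fit_logistic(cbind(terms, covm)[keep, , drop = FALSE], y[keep])
    tc <- tidy(crude) %>% dplyr::filter(.data$term == trm)
    ta <- tidy(adj) %>% dplyr::filter(.data$term == trm)
    tibble(
      score = score, contrast = contrast, term = trm,
      n_cases = sum(y[keep][terms[keep, trm] == 1] == 1),
      n_controls = sum(y[keep][terms[keep, trm] == 1] == 0),
      or_crude = tc$or, conf.low_crude = tc$conf.low, conf.high_crude = tc$conf.high,
      p_crude = tc$p.value,
      or_adjusted = ta$or, conf.low_adjusted = ta$conf.low,
      conf.high_adjusted = ta$conf.high, p_adjusted = ta$p.value
    )
  })
  if (contrast != "per_unit") {
    ord <- as.numeric(cat) - 1  # 0/1/2 ordinal score
    trend <- fit_logistic(cbind(trend = ord, covm)[keep, , drop = FALSE], y[keep])
    res$p_trend <- (tidy(trend) %>% dplyr::filter(.data$term == "trend"))$p.value
  }
  res
}

#' Stratified GRS association with heterogeneity tests
#'
#' Fits the adjusted high-vs-low/medium (or per-unit) model independently in
#' each stratum (the stratifier is dropped from the covariates) and tests
#' heterogeneity of the log-OR between strata with the two-sample Z test
#' \eqn{Z = (b_1 - b_2)/\sqrt{se_1^2 + se_2^2}}. With more than two strata,
#' pairwise Z against the first stratum is reported plus an overall
#' Cochran-Q.
#'
#' @inheritParams grs_association
#' @param stratify Column to stratify by (`"sex"` or `"age_group"`).
#' @return List with `strata` (per-stratum estimates) and `heterogeneity`.
#' @export
stratified_grs <- function(cohort, profiles, stratify = c("sex", "age_group"),
                           score = c("unweighted", "weighted"),
                           contrast = c("high_vs_rest", "per_unit"),
                           covariates = c("age_group", "sex", "maternal_edu",
                                          "paternal_edu", "income"),
                           cutpoints = NULL) {
  stratify <- match.arg(stratify)
  score <- match.arg(score)
  contrast <- match.arg(contrast)
  covariates <- setdiff(covariates, stratify)
  # categorise on the full sample so strata share cutpoints
  if (contrast == "high_vs_rest" && is.null(cutpoints)) {
    cutpoints <- attr(categorize_grs(profiles[[score]]), "cutpoints")
  }
  levels <- unique(cohort[[stratify]][!is.na(cohort[[stratify]])])
  per <- purrr::map(levels, function(lv) {
    idx <- !is.na(cohort[[stratify]]) & cohort[[stratify]] == lv
    sub <- cohort[idx, , drop = FALSE]
    if (length(unique(sub$status)) < 2) {
      warn(sprintf("stratum %s has a single status; skipped", lv))
      return(NULL)
    }
    est <- grs_association(sub, profiles[idx, , drop = FALSE], score = score,
                           contrast = contrast, covariates = covariates,
                           cutpoints = cutpoints)
    est$stratum <- as.character(lv)
    est
  })
  per <- per[!vapply(per, is.null, logical(1))]
  strata <- dplyr::bind_rows(per)
  b <- log(strata$or_adjusted)
  se <- (log(strata$conf.high_adjusted) - log(strata$conf.low_adjusted)) / (2 * qnorm(0.975))
  het <- NULL
  if (nrow(strata) >= 2) {
    het <- purrr::map_dfr(2:nrow(strata), function(i) {
      tibble(
        stratum_1 = strata$stratum[1], stratum_2 = strata$stratum[i],
        z = heterogeneity_z(b[1], se[1], b[i], se[i]),
        p = 2 * pnorm(-abs(heterogeneity_z(b[1], se[1], b[i], se[i])))
      )
    })
    if (nrow(strata) > 2) {
      w <- 1 / se^2
      q <- sum(w * (b - sum(w * b) / sum(w))^2)
      attr(het, "cochran_q") <- c(
        Q = q, df = nrow(strata) - 1,
        p = pchisq(q, df = nrow(strata) - 1, lower.tail = FALSE)
      )
    }
  }
  list(strata = strata, heterogeneity = het)
}

#' Heterogeneity Z statistic for two independent coefficients
#'
#' @param b1,b2 Coefficients. @param se1,se2 Their standard errors.
#' @return \eqn{(b_1 - b_2)/\sqrt{se_1^2 + se_2^2}}.
#' @export
heterogeneity_z <- function(b1, se1, b2, se2) {
  (b1 - b2) / sqrt(se1^2 + se2^2)
}
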