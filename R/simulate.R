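# Synthetic frequency-matched case-control cohorts. The generator draws a
# prospective population under a logistic disease model and then samples cases
# and frequency-matched controls from it, which is the design under which
# case-control logistic odds ratios remain valid.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_cohort()]. The defaults describe a
#' "study-like" childhood-obesity cohort: 1123 cases and 1231 controls, twelve
#' biallelic variants in the leptin-melanocortin pathway of which four carry
#' per-risk-allele log-odds effects (0.268, 0.217, 0.110, 0.044 — the additive
#' per-allele coefficients of the four score variants), binary lifestyle
#' exposures with inadequate-activity prevalence 0.86 and inadequate-sleep
#' prevalence 0.80, and covariate margins matching the study's descriptive
#' table. Genotypes are drawn under Hardy-Weinberg equilibrium at the stated
#' ALT frequency unless an inbreeding-style departure `f` is given, in which
#' case heterozygote probability is scaled by `1 - f`.
#'
#' @param n_cases,n_controls Target sample sizes.
#' @param variants Tibble with columns `variant_id`, `gene_label`, `ref_allele`,
#'   `alt_allele`, `risk_allele`, `alt_freq` (ALT-allele frequency in (0,1)),
#'   `beta` (per-risk-allele log-odds) and optionally `hwe_departure`.
#' @param baseline_log_odds Intercept of the disease logit; the default gives a
#'   marginal prevalence near 0.15 under the default effects.
#' @param covariates Named list of category-probability vectors for `sex`,
#'   `age_group`, `maternal_edu`, `paternal_edu`, `income`. `school` is derived
#'   from `age_group` (primary/junior/senior bands).
#' @param lifestyle List with `prev_inadequate_activity`,
#'   `prev_inadequate_sleep` and log-odds effects `beta_activity`,
#'   `beta_sleep` of the inadequate level.
#' @param interactions Optional list of terms
#'   `list(variants=, threshold=, lifestyle=, beta=)`: samples whose
#'   risk-allele count over `variants` is `>= threshold` *and* whose
#'   `lifestyle` is inadequate receive `beta` extra log-odds.
#' @param missing_rates Named per-field missing-completely-at-random rates
#'   applied by [simulate_cohort()].
#' @param matching_factors Factors used for frequency matching of controls.
#' @param seed Integer seed; a fixed seed makes the whole draw reproducible.
#' @return A `grsxe_sim_config` list.
#' @export
sim_config <- function(n_cases = 1123,
                       n_controls = 1231,
                       variants = default_sim_variants(),
                       baseline_log_odds = -2.25,
                       covariates = default_sim_covariates(),
                       lifestyle = list(
                         prev_inadequate_activity = 0.86,
                         prev_inadequate_sleep = 0.80,
                         beta_activity = 0.15,
                         beta_sleep = 0.15
                       ),
                       interactions = list(),
                       missing_rates = c(
                         physical_activity = 0.013, sleep = 0.015,
                         genotype = 0.001
                       ),
                       matching_factors = c("sex", "age_group", "school"),
                       seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0)
  stopifnot(all(variants$alt_freq > 0 & variants$alt_freq < 1))
  stopifnot(all(variants$risk_allele == variants$ref_allele |
                  variants$risk_allele == variants$alt_allele))
  if (is.null(variants$hwe_departure)) variants$hwe_departure <- 0
  for (p in covariates) stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-8)
  structure(
    list(
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      variants = variants, baseline_log_odds = baseline_log_odds,
      covariates = covariates, lifestyle = lifestyle,
      interactions = interactions, missing_rates = missing_rates,
      matching_factors = matching_factors, seed = as.integer(seed)
    ),
    class = "grsxe_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_sim_variants <- function() {
  # Four effect variants (risk allele and additive beta from the study's score
  # definition) plus eight null variants. ALT frequencies are plausible
  # southern-Han values; rs6713532's risk allele is the REF allele so the
  # orientation path is exercised.
  tibble(
    variant_id = c("rs17782313", "rs12970134", "rs1137101", "rs6713532",
                   "rs1349419", "rs2167270", "rs11208659", "rs1137100",
                   "rs16141", "rs6127698", "rs3746619", "rs8087522"),
    gene_label = c("MC4R", "MC4R", "LEPR", "POMC",
                   "LEP", "LEP", "LEPR", "LEPR",
                   "NPY", "MC3R", "MC3R", "MC4R"),
    ref_allele = c("T", "G", "G", "T", "C", "G", "T", "A", "T", "T", "C", "G"),
    alt_allele = c("C", "A", "A", "C", "T", "A", "C", "G", "C", "G", "A", "A"),
    risk_allele = c("C", "A", "A", "T", "T", "A", "C", "G", "C", "G", "A", "A"),
    alt_freq = c(0.20, 0.17, 0.21, 0.78, 0.45, 0.18, 0.12, 0.25,
                 0.42, 0.35, 0.30, 0.28),
    beta = c(0.268, 0.217, 0.110, 0.044, 0, 0, 0, 0, 0, 0, 0, 0),
    hwe_departure = 0
  )
}

#' @rdname sim_config
#' @export
default_sim_covariates <- function() {
  list(
    sex = c(boy = 0.681, girl = 0.319),
    age_group = c("7-8" = 0.19, "11-14" = 0.488, "15-18" = 0.322),
    maternal_edu = c(high_school_or_below = 0.487, junior_college_or_above = 0.513),
    paternal_edu = c(high_school_or_below = 0.469, junior_college_or_above = 0.531),
    income = c(low = 0.30, medium = 0.374, high = 0.326)
  )
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

risk_dosage_from_alt <- function(alt_dosage, risk_is_alt) {
  if (risk_is_alt) alt_dosage else 2L - alt_dosage
}

#' Simulate a prospective population pool
#'
#' Draws `n_pool` individuals with covariates, lifestyle exposures and
#' genotypes, computes the latent disease probability from the logistic model
#' in `config`, and assigns disease status by a Bernoulli draw. The returned
#' pool carries the latent probability in `.p_disease`.
#'
#' @param config A [sim_config()].
#' @param n_pool Pool size.
#' @return A cohort-shaped tibble with `status`, covariates, lifestyle,
#'   one ALT-dosage column per variant, and `.p_disease`.
#' @export
simulate_population <- function(config, n_pool = 20000L) {
  stopifnot(inherits(config, "grsxe_sim_config"))
  withr_seed(config$seed, {
    cov <- config$covariates
    pool <- tibble(
      sample_id = sprintf("S%06d", seq_len(n_pool)),
      sex = sample_cat(n_pool, cov$sex),
      age_group = sample_cat(n_pool, cov$age_group),
      maternal_edu = sample_cat(n_pool, cov$maternal_edu),
      paternal_edu = sample_cat(n_pool, cov$paternal_edu),
      income = sample_cat(n_pool, cov$income)
    )
    pool$school <- unname(c("7-8" = "primary", "11-14" = "junior",
                            "15-18" = "senior")[pool$age_group])
    ls <- config$lifestyle
    pool$physical_activity <- ifelse(
      runif(n_pool) < ls$prev_inadequate_activity, "inadequate", "adequate")
    pool$sleep <- ifelse(
      runif(n_pool) < ls$prev_inadequate_sleep, "inadequate", "adequate")

    eta <- rep(config$baseline_log_odds, n_pool)
    vt <- config$variants
    for (i in seq_len(nrow(vt))) {
      f <- vt$alt_freq[i]
      fc <- vt$hwe_departure[i]
      # inbreeding-style genotype probabilities: AA, Aa, aa
      p_gt <- c((1 - f)^2 + fc * f * (1 - f),
                2 * f * (1 - f) * (1 - fc),
                f^2 + fc * f * (1 - f))
      d <- sample(0:2, n_pool, replace = TRUE, prob = p_gt)
      pool[[vt$variant_id[i]]] <- as.integer(d)
      if (vt$beta[i] != 0) {
        rd <- risk_dosage_from_alt(d, vt$risk_allele[i] == vt$alt_allele[i])
        eta <- eta + vt$beta[i] * rd
      }
    }
    eta <- eta + ls$beta_activity * (pool$physical_activity == "inadequate")
    eta <- eta + ls$beta_sleep * (pool$sleep == "inadequate")
    for (term in config$interactions) {
      rc <- rowSums(vapply(term$variants, function(v) {
        i <- match(v, vt$variant_id)
        risk_dosage_from_alt(pool[[v]], vt$risk_allele[i] == vt$alt_allele[i])
      }, numeric(n_pool)))
      hit <- rc >= term$threshold & pool[[term$lifestyle]] == "inadequate"
      eta <- eta + term$beta * hit
    }
    pool$.p_disease <- stats::plogis(eta)
    pool$status <- as.integer(runif(n_pool) < pool$.p_disease)
    dplyr::relocate(pool, "sample_id", "status")
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Frequency-match controls to cases
#'
#' Selects `n_cases` cases at random and `n_controls` controls whose joint
#' distribution over `matching_factors` matches the selected cases' to the
#' limit of available control counts. Cells where the control pool falls short
#' trigger a warning and the deficit is reallocated proportionally across the
#' remaining cells. Per-cell targets, achieved counts and shortfalls are
#' attached as the `"matching"` attribute.
#'
#' @param pool Tibble from [simulate_population()].
#' @param n_cases,n_controls Target counts.
#' @param matching_factors Character vector of matching columns; empty means a
#'   simple random sample of controls.
#' @param seed Integer seed.
#' @return The matched case-control cohort tibble.
#' @export
frequency_match <- function(pool, n_cases, n_controls,
                            matching_factors = c("sex", "age_group", "school"),
                            seed = 1L) {
  if (!any(pool$status == 1) || !any(pool$status == 0)) {
    abort("pool must contain both cases and controls")
  }
  if (sum(pool$status == 1) < n_cases) {
    abort(sprintf(
      "pool yielded %d cases but %d requested; enlarge the pool or raise baseline_log_odds",
      sum(pool$status == 1), n_cases
    ))
  }
  withr_seed(seed, {
    cases <- pool %>%
      dplyr::filter(.data$status == 1) %>%
      dplyr::slice_sample(n = n_cases)
    controls_pool <- dplyr::filter(pool, .data$status == 0)
    if (length(matching_factors) == 0) {
      controls <- dplyr::slice_sample(controls_pool, n = min(n_controls, nrow(controls_pool)))
      matching <- NULL
    } else {
      cell_of <- function(d) do.call(paste, c(d[matching_factors], sep = "\r"))
      case_cells <- table(cell_of(cases))
      target <- largest_remainder(as.numeric(case_cells) / n_cases * n_controls)
      names(target) <- names(case_cells)
      ctrl_cell <- cell_of(controls_pool)
      avail <- table(factor(ctrl_cell, levels = names(target)))
      got <- pmin(target, as.numeric(avail))
      deficit <- sum(target) - sum(got)
      if (deficit > 0) {
        warn(sprintf(
          "frequency_match: %d control(s) short in %d cell(s); reallocating proportionally",
          deficit, sum(got < target)
        ))
        while (deficit > 0) {
          room <- as.numeric(avail) - got
          if (all(room <= 0)) break
          add <- largest_remainder(pmin(room, got / max(sum(got), 1) * deficit + (room > 0) * 1e-9))
          add <- pmin(add, room)
          if (sum(add) == 0) {  # put one in the roomiest cell
            i <- which.max(room)
            add[i] <- 1
          }
          got <- got + add
          deficit <- sum(target) - sum(got)
        }
      }
      picks <- unlist(lapply(seq_along(target), function(i) {
        idx <- which(ctrl_cell == names(target)[i])
        if (got[i] > 0) sample(idx, got[i]) else integer(0)
      }))
      controls <- controls_pool[picks, ]
      matching <- tibble(
        cell = gsub("\r", "/", names(target)),
        target = as.integer(target),
        achieved = as.integer(got),
        shortfall = as.integer(target - got)
      )
    }
    cohort <- dplyr::bind_rows(cases, controls)
    attr(cohort, "matching") <- matching
    cohort
  })
}

# Integer apportionment preserving the total (largest-remainder rule).
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  fl
}

#' Mask fields completely at random
#'
#' @param cohort Cohort tibble.
#' @param rates Named vector of per-field missingness rates in `[0,1)`; the
#'   special name `genotype` applies to every variant dosage column.
#' @param variant_ids Dosage columns covered by the `genotype` rate.
#' @param seed Integer seed.
#' @return The cohort with values masked; per-field masked counts in the
#'   `"n_masked"` attribute.
#' @export
inject_missingness <- function(cohort, rates, variant_ids = character(), seed = 1L) {
  stopifnot(all(rates >= 0 & rates < 1))
  withr_seed(seed, {
    fields <- list()
    for (nm in names(rates)) {
      cols <- if (nm == "genotype") variant_ids else nm
      for (col in intersect(cols, names(cohort))) {
        fields[[col]] <- rates[[nm]]
      }
    }
    n_masked <- integer(0)
    for (col in names(fields)) {
      mask <- runif(nrow(cohort)) < fields[[col]]
      cohort[[col]][mask] <- NA
      n_masked[col] <- sum(mask)
    }
    attr(cohort, "n_masked") <- n_masked
    cohort
  })
}

#' Simulate a full frequency-matched case-control cohort
#'
#' Convenience wrapper: draws a pool with [simulate_population()], selects
#' cases and frequency-matched controls with [frequency_match()], and applies
#' [inject_missingness()]. The latent probability column is dropped.
#'
#' @param config A [sim_config()].
#' @param n_pool Pool size; the default scales with the requested cohort and
#'   the expected prevalence.
#' @return A cohort tibble of `n_cases + n_controls` rows; the variant table is
#'   attached as the `"variants"` attribute.
#' @export
simulate_cohort <- function(config = sim_config(), n_pool = NULL) {
  stopifnot(inherits(config, "grsxe_sim_config"))
  if (is.null(n_pool)) {
    n_pool <- max(20000L, as.integer(10 * (config$n_cases + config$n_controls)))
  }
  pool <- simulate_population(config, n_pool = n_pool)
  cohort <- frequency_match(
    pool, config$n_cases, config$n_controls,
    matching_factors = config$matching_factors,
    seed = derive_seed(config$seed, "match")
  )
  cohort <- inject_missingness(
    cohort, config$missing_rates,
    variant_ids = config$variants$variant_id,
    seed = derive_seed(config$seed, "missing")
  )
  cohort$.p_disease <- NULL
  vt <- config$variants
  vt$maf <- pmin(vt$alt_freq, 1 - vt$alt_freq)
  attr(cohort, "variants") <- vt
  cohort
}
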