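# Crossover (joint-effect) analysis of a binary GRS with a binary lifestyle
# exposure: additive-scale (RERI, AP) and multiplicative-scale (IOR)
# interaction measures with stratified-bootstrap percentile CIs.

#' Relative excess risk of interaction
#'
#' `RERI = OR11 - OR10 - OR01 + 1`; zero under joint additivity of the two
#' exposures' excess risks.
#'
#' @param or11 Adjusted OR of the doubly exposed cell vs the doubly unexposed
#'   reference.
#' @param or10,or01 Adjusted ORs of the singly exposed cells.
#' @return The RERI.
#' @export
reri <- function(or11, or10, or01) {
  stopifnot(or11 > 0, or10 > 0, or01 > 0)
  or11 - or10 - or01 + 1
}

#' Attributable proportion of interaction
#'
#' `AP = RERI / OR11`: the share of the joint-exposure effect attributable to
#' additive interaction.
#'
#' @param reri_value A RERI.
#' @param or11 The joint-exposure OR (> 0).
#' @return The AP.
#' @export
ap <- function(reri_value, or11) {
  stopifnot(or11 > 0)
  reri_value / or11
}

#' Interaction odds ratio (multiplicative scale)
#'
#' `IOR = OR11 / (OR10 * OR01)`; one under joint multiplicativity.
#'
#' @inheritParams reri
#' @return The IOR.
#' @export
ior <- function(or11, or10, or01) {
  stopifnot(or11 > 0, or10 > 0, or01 > 0)
  or11 / (or10 * or01)
}

# Build the three joint-exposure indicators (G1E0, G0E1, G1E1) and the cell
# counts; rows with missing exposure or score are dropped.
crossover_design <- function(cohort, grs_high, exposed,
                             covariates = c("age_group", "sex", "maternal_edu",
                                            "paternal_edu", "income")) {
  keep <- !is.na(grs_high) & !is.na(exposed)
  if (!any(keep)) abort("exposure (or score) missing for every sample")
  g <- as.integer(grs_high[keep]); e <- as.integer(exposed[keep])
  y <- check_status(cohort$status[keep])
  g_cell <- c(0L, 0L, 1L, 1L)
  e_cell <- c(0L, 1L, 0L, 1L)
  n_cases_cell <- vapply(1:4, function(i) {
    sum(y == 1 & g == g_cell[i] & e == e_cell[i])
  }, integer(1))
  n_controls_cell <- vapply(1:4, function(i) {
    sum(y == 0 & g == g_cell[i] & e == e_cell[i])
  }, integer(1))
  cells <- tibble(
    grs = c("low/medium", "low/medium", "high", "high"),
    exposure = c("unexposed", "exposed", "unexposed", "exposed"),
    g = g_cell, e = e_cell,
    n_cases = n_cases_cell, n_controls = n_controls_cell
  )
  empty <- cells$n_cases + cells$n_controls == 0
  if (any(empty)) {
    abort(paste0("empty crossover cell: ",
                 paste(cells$grs[empty], cells$exposure[empty], sep = "/",
                       collapse = "; ")))
  }
  covm <- covariate_matrix(cohort[keep, , drop = FALSE], covariates)
  X <- cbind(
    g1e0 = as.numeric(g == 1 & e == 0),
    g0e1 = as.numeric(g == 0 & e == 1),
    g1e1 = as.numeric(g == 1 & e == 1),
    covm
  )
  ok <- stats::complete.cases(X)
  list(X = X[ok, , drop = FALSE], y = y[ok], cells = cells, n = sum(ok))
}

#' Crossover table and adjusted joint-effect odds ratios
#'
#' One adjusted logistic model with three indicators (G high & E unexposed,
#' G low/medium & E exposed, G high & E exposed) against the joint reference
#' cell, plus the four cell counts. "Exposed" is the inadequate level of the
#' lifestyle factor.
#'
#' @param cohort Cohort tibble.
#' @param grs_high Logical/0-1 vector: high-GRS indicator per sample (NA
#'   drops the sample).
#' @param exposure Column name of the lifestyle factor (`"sleep"` or
#'   `"physical_activity"`), whose value `"inadequate"` is the exposed level.
#' @param covariates Adjustment covariates.
#' @return A `grsxe_crossover` list: `cells` (counts per G x E cell),
#'   `estimates` (tibble of or10/or01/or11 with CIs), `fit`, `n`.
#' @export
crossover_table <- function(cohort, grs_high, exposure,
                            covariates = c("age_group", "sex", "maternal_edu",
                                           "paternal_edu", "income")) {
  exposed <- exposure_indicator(cohort, exposure)
  des <- crossover_design(cohort, grs_high, exposed, covariates)
  fit <- fit_logistic(des$X, des$y)
  td <- tidy(fit)
  pick <- function(trm) td[td$term == trm, ]
  estimates <- dplyr::bind_rows(
    dplyr::mutate(pick("g1e0"), cell = "or10"),
    dplyr::mutate(pick("g0e1"), cell = "or01"),
    dplyr::mutate(pick("g1e1"), cell = "or11")
  ) %>%
    dplyr::select("cell", "or", "conf.low", "conf.high", "p.value")
  structure(
    list(cells = des$cells, estimates = estimates, fit = fit,
         n = des$n, exposure = exposure),
    class = "grsxe_crossover"
  )
}

exposure_indicator <- function(cohort, exposure) {
  if (!exposure %in% names(cohort)) abort(paste0("no column ", exposure))
  x <- cohort[[exposure]]
  ifelse(is.na(x), NA, as.integer(x == "inadequate"))
}

#' @export
print.grsxe_crossover <- function(x, ...) {
  cat(sprintf("<grsxe_crossover> exposure = %s, n = %d\n", x$exposure, x$n))
  print(x$cells)
  print(x$estimates)
  invisible(x)
}

#' Interaction measures with stratified-bootstrap confidence intervals
#'
#' Computes RERI, AP and IOR from the adjusted crossover model and, if
#' `B > 0`, percentile 95% CIs from `B` bootstrap resamples of whole samples
#' drawn with replacement separately within cases and controls (preserving
#' the case-control design). Resamples whose crossover model fails (empty
#' cell or non-convergence) are dropped and counted; more than 10% dropped
#' raises a warning.
#'
#' @inheritParams crossover_table
#' @param B Number of bootstrap replications.
#' @param seed Integer seed.
#' @param stratified Resample within status groups (default) or from the
#'   pooled sample.
#' @return A `grsxe_interaction` list: the crossover result plus a
#'   `measures` tibble (`reri`, `ap`, `ior` with CIs and CI-exclusion
#'   significance flags), `n_bootstrap`, `n_dropped`, `seed`.
#' @export
bootstrap_interaction <- function(cohort, grs_high, exposure,
                                  covariates = c("age_group", "sex", "maternal_edu",
                                                 "paternal_edu", "income"),
                                  B = 1000L, seed = 1L, stratified = TRUE) {
  cross <- crossover_table(cohort, grs_high, exposure, covariates)
  ors <- setNames(cross$estimates$or, cross$estimates$cell)
  point <- c(
    reri = reri(ors[["or11"]], ors[["or10"]], ors[["or01"]]),
    ap = ap(reri(ors[["or11"]], ors[["or10"]], ors[["or01"]]), ors[["or11"]]),
    ior = ior(ors[["or11"]], ors[["or10"]], ors[["or01"]])
  )
  ci <- matrix(NA_real_, 3, 2, dimnames = list(names(point), c("low", "high")))
  n_dropped <- NA_integer_
  if (B > 0) {
    draws <- matrix(NA_real_, B, 3, dimnames = list(NULL, names(point)))
    withr_seed(seed, {
      idx_case <- which(cohort$status == 1)
      idx_ctrl <- which(cohort$status == 0)
      for (b in seq_len(B)) {
        idx <- if (stratified) {
          c(sample(idx_case, replace = TRUE), sample(idx_ctrl, replace = TRUE))
        } else {
          sample(nrow(cohort), replace = TRUE)
        }
        cb <- try(crossover_table(cohort[idx, , drop = FALSE], grs_high[idx],
                                  exposure, covariates), silent = TRUE)
        if (inherits(cb, "try-error") || !cb$fit$converged) next
        ob <- setNames(cb$estimates$or, cb$estimates$cell)
        rb <- reri(ob[["or11"]], ob[["or10"]], ob[["or01"]])
        draws[b, ] <- c(rb, rb / ob[["or11"]],
                        ior(ob[["or11"]], ob[["or10"]], ob[["or01"]]))
      }
    })
    ok <- stats::complete.cases(draws)
    n_dropped <- B - sum(ok)
    if (n_dropped > 0.1 * B) {
      warn(sprintf("%d of %d bootstrap resamples dropped", n_dropped, B))
    }
    for (m in names(point)) {
      ci[m, ] <- quantile(draws[ok, m], c(0.025, 0.975), names = FALSE)
    }
  }
  measures <- tibble(
    measure = names(point),
    estimate = unname(point),
    conf.low = ci[, "low"],
    conf.high = ci[, "high"],
    null_value = c(0, 0, 1),
    significant = !is.na(ci[, "low"]) &
      (ci[, "low"] > c(0, 0, 1) | ci[, "high"] < c(0, 0, 1))
  )
  structure(
    list(cells = cross$cells, estimates = cross$estimates, fit = cross$fit,
         n = cross$n, exposure = cross$exposure, measures = measures,
         n_bootstrap = B, n_dropped = n_dropped, seed = seed),
    class = c("grsxe_interaction", "grsxe_crossover")
  )
}

#' @export
print.grsxe_interaction <- function(x, ...) {
  NextMethod()
  print(x$measures)
  invisible(x)
}

#' Tidy an interaction result
#'
#' @param x A `grsxe_interaction`.
#' @param ... Unused.
#' @return The `measures` tibble (RERI, AP, IOR with CIs).
#' @export
tidy.grsxe_interaction <- function(x, ...) x$measures
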