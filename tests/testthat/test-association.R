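# Descriptive tests, crude ORs, genotype codings, the IRLS fitter, and the
# label-permutation correction.

test_that("pearson_chi2 has no continuity correction and is transpose-invariant", {
  tab <- matrix(c(144, 964, 171, 1045), 2, byrow = TRUE)
  res <- pearson_chi2(tab)
  expect_equal(res$statistic, unname(chisq.test(tab, correct = FALSE)$statistic))
  expect_equal(pearson_chi2(t(tab))$statistic, res$statistic)
  # identical row distributions -> 0
  expect_equal(pearson_chi2(matrix(c(10, 20, 10, 20), 2, byrow = TRUE))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
})

test_that("two_sample_t is the pooled-variance test with Welch behind a flag", {
  set.seed(3)
  x <- rnorm(50); y <- rnorm(60, sd = 2)
  expect_equal(
    two_sample_t(x, y)$statistic,
    unname(t.test(x, y, var.equal = TRUE)$statistic)
  )
  expect_equal(
    two_sample_t(x, y, welch = TRUE)$df,
    unname(t.test(x, y)$parameter)
  )
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("crude_or symmetry, inversion, and zero-cell handling", {
  expect_equal(crude_or(5, 5, 5, 5)$or, 1)
  o <- crude_or(30, 70, 20, 80)
  # exposure relabelling inverts the OR
  expect_equal(crude_or(70, 30, 80, 20)$or, 1 / o$or)
  # simultaneous row and column swap leaves it unchanged
  expect_equal(crude_or(80, 20, 70, 30)$or, o$or)
  expect_error(crude_or(0, 10, 10, 10), "zero cell")
  expect_true(crude_or(0, 10, 10, 10, haldane = TRUE)$or > 0)
})

test_that("genotype codings follow the model definitions", {
  expect_equal(unname(code_genotype(1L, "dominant")[1, 1]), 1)
  expect_equal(unname(code_genotype(1L, "recessive")[1, 1]), 0)
  expect_equal(code_genotype(2L, "genotypic")[1, ], c(het = 0, hom = 1))
  expect_equal(unname(code_genotype(c(0L, 1L, 2L), "additive")[, 1]), c(0, 1, 2))
  expect_true(is.na(code_genotype(NA_integer_, "dominant")[1, 1]))
})

test_that("IRLS agrees with glm to 1e-6 and recovers the 2x2 closed form", {
  # intercept-only on a balanced sample gives logit(0.5) = 0
  f0 <- fit_logistic(matrix(numeric(0), 100, 0), rep(c(0L, 1L), 50))
  expect_lt(abs(f0$coefficients[["(Intercept)"]]), 1e-10)

  # saturated 2x2: coefficient equals the crude log-OR (cells from a
  # published high-vs-low/medium contrast: 350/772 cases, 300/928 controls)
  x <- rep(c(1, 0, 1, 0), c(350, 772, 300, 928))
  y <- rep(c(1L, 1L, 0L, 0L), c(350, 772, 300, 928))
  f <- fit_logistic(cbind(exposed = x), y)
  expect_equal(f$coefficients[["exposed"]], log(350 * 928 / (772 * 300)),
               tolerance = 1e-8)
  expect_equal(exp(f$coefficients[["exposed"]]), crude_or(350, 772, 300, 928)$or,
               tolerance = 1e-8)

  # library oracle on simulated designs
  set.seed(13)
  for (i in 1:5) {
    n <- 300
    X <- cbind(a = rbinom(n, 2, 0.3), b = rnorm(n), c = rbinom(n, 1, 0.5))
    yy <- rbinom(n, 1, plogis(-0.4 + 0.3 * X[, 1] - 0.2 * X[, 2]))
    fit <- fit_logistic(X, yy)
    ref <- glm(yy ~ X, family = binomial)
    expect_lt(max(abs(fit$coefficients - coef(ref))), 1e-6)
    expect_lt(max(abs(fit$std.error - summary(ref)$coefficients[, 2])), 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  }
})

test_that("separation and rank deficiency are flagged, not repaired", {
  y <- rep(c(0L, 1L), each = 20)
  x <- as.numeric(y)  # perfect separation
  f <- fit_logistic(cbind(x = x), y)
  expect_true(f$separation)
  expect_false(f$converged)
  expect_error(fit_logistic(cbind(a = x, b = 2 * x), y), "rank")
})

test_that("tidy/glance expose Wald inference on both scales", {
  set.seed(14)
  X <- cbind(x = rbinom(200, 2, 0.3))
  y <- rbinom(200, 1, 0.5)
  f <- fit_logistic(X, y)
  td <- tidy(f)
  expect_tibble(td)
  expect_equal(td$or, exp(td$estimate))
  expect_true(all(td$conf.low <= td$or & td$or <= td$conf.high))
  expect_true(glance(f)$converged)
})

test_that("permutation p has the add-one floor and hits it for strong effects", {
  set.seed(15)
  n <- 2000
  x <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + log(2) * x))
  p <- permutation_p_association(cbind(x = x), y, term = "x", B = 99, seed = 1)
  expect_equal(p, 1 / 100)
})

test_that("adjusted Wald type-I error is calibrated under the null", {
  set.seed(16)
  n <- 1000
  rejects <- vapply(seq_len(1000), function(i) {
    y <- rep(c(0L, 1L), each = n / 2)
    X <- cbind(
      g = rbinom(n, 2, 0.25),
      sex = rbinom(n, 1, 0.68),
      edu = rbinom(n, 1, 0.5)
    )
    td <- tidy(fit_logistic(X, y))
    td$p.value[td$term == "g"] < 0.05
  }, logical(1))
  expect_gte(mean(rejects), 0.03)
  expect_lte(mean(rejects), 0.07)
})

test_that("association_scan orients to the risk allele and reports all models", {
  co <- small_cohort(200, 200, seed = 17)
  vt <- default_sim_variants()[c(1, 4), ]
  res <- association_scan(co, vt, B = 0)
  expect_equal(sort(unique(res$model)),
               sort(c("genotypic", "dominant", "recessive", "additive")))
  # rs6713532's risk allele is REF: its additive OR must equal the flipped
  # ALT coding's inverse
  alt_or <- {
    X <- cbind(additive = as.numeric(co$rs6713532),
               covariate_matrix(co))
    keep <- complete.cases(X)
    td <- tidy(fit_logistic(X[keep, , drop = FALSE], co$status[keep]))
    td$or[td$term == "additive"]
  }
  risk_or <- res$or[res$variant_id == "rs6713532" & res$model == "additive"]
  expect_equal(risk_or, 1 / alt_or, tolerance = 1e-8)
})
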