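# Genetic risk scores: orientation, totals, quartile bins, association,
# stratified heterogeneity.

test_that("orient_to_risk flips only when the risk allele is REF", {
  alt_risk <- tibble::tibble(variant_id = "v", ref_allele = "T",
                             alt_allele = "C", risk_allele = "C")
  ref_risk <- dplyr::mutate(alt_risk, risk_allele = "T")
  expect_equal(orient_to_risk(c(0L, 1L, 2L, NA), alt_risk), c(0L, 1L, 2L, NA))
  expect_equal(orient_to_risk(c(0L, 1L, 2L, NA), ref_risk), c(2L, 1L, 0L, NA))
  expect_error(orient_to_risk(1L, dplyr::mutate(alt_risk, risk_allele = "G")),
               "neither")
})

test_that("GRS totals match the published coefficient arithmetic", {
  w <- study_weights()
  # one risk allele at each of the four variants; rs6713532 risk allele is
  # REF so its ALT dosage 1 still counts one risk allele
  co <- tibble::tibble(
    sample_id = c("a", "b", "c"), status = c(1L, 0L, 1L),
    rs17782313 = c(1L, 0L, 2L), rs12970134 = c(1L, 0L, 2L),
    rs1137101 = c(1L, 0L, 2L), rs6713532 = c(1L, 2L, 0L)
  )
  prof <- compute_grs(co, w)
  expect_equal(prof$unweighted, c(4L, 0L, 8L))
  expect_equal(prof$weighted, c(0.639, 0, 1.278), tolerance = 1e-12)
  expect_true(all(prof$complete))
})

test_that("samples missing any component variant carry no score", {
  co <- tibble::tibble(
    sample_id = c("a", "b"), status = c(1L, 0L),
    rs17782313 = c(1L, NA), rs12970134 = c(0L, 1L),
    rs1137101 = c(0L, 1L), rs6713532 = c(2L, 2L)
  )
  prof <- compute_grs(co, study_weights())
  expect_false(prof$complete[2])
  expect_true(is.na(prof$unweighted[2]) && is.na(prof$weighted[2]))
  expect_error(compute_grs(dplyr::select(co, sample_id, status), study_weights()),
               "no component")
})

test_that("unweighted GRS equals weighted GRS under unit betas", {
  co <- small_cohort(150, 150, seed = 33)
  w <- dplyr::mutate(study_weights(), beta = 1)
  prof <- compute_grs(co, w)
  expect_equal(prof$weighted, as.numeric(prof$unweighted))
})

test_that("GRS is invariant to REF/ALT orientation of the input file", {
  co <- small_cohort(100, 100, seed = 34)
  w <- study_weights()
  prof1 <- compute_grs(co, w)
  # flip rs17782313's file orientation: swap REF/ALT and complement dosages
  co2 <- dplyr::mutate(co, rs17782313 = 2L - rs17782313)
  w2 <- dplyr::mutate(
    w,
    ref_allele = ifelse(variant_id == "rs17782313", "C", ref_allele),
    alt_allele = ifelse(variant_id == "rs17782313", "T", alt_allele)
  )
  prof2 <- compute_grs(co2, w2)
  expect_identical(prof1$unweighted, prof2$unweighted)
  expect_equal(prof1$weighted, prof2$weighted)
})

test_that("quartile categorisation snaps to whole-score bins", {
  # a score distribution like the study's: 18% zeros, heavy 1-2, tail to 6
  scores <- rep(0:6, c(428, 600, 672, 400, 180, 60, 10))
  cat <- categorize_grs(scores)
  expect_equal(unique(scores[cat == "low"]), 0)
  expect_equal(sort(unique(scores[cat == "medium"])), c(1, 2))
  expect_equal(sort(unique(scores[cat == "high"])), 3:6)
  expect_equal(unname(attr(cat, "cutpoints")), c(1, 3))
  expect_error(categorize_grs(rep(1, 10)), "degenerate")
  # explicit cutpoints pass through
  cat2 <- categorize_grs(scores, cutpoints = c(2, 5))
  expect_equal(sort(unique(scores[cat2 == "high"])), 5:6)
})

test_that("mean GRS of cases exceeds controls when all betas are positive", {
  co <- small_cohort(1000, 1000, seed = 35)
  prof <- compute_grs(co, study_weights())
  m <- tapply(prof$unweighted, prof$status, mean, na.rm = TRUE)
  expect_gt(m[["1"]], m[["0"]])
})

test_that("grs_association fits the published contrasts and a trend", {
  co <- small_cohort(400, 400, seed = 36)
  prof <- compute_grs(co, study_weights())
  three <- grs_association(co, prof, "unweighted", "three_level")
  expect_equal(three$term, c("medium", "high"))
  expect_true(all(three$p_trend > 0 & three$p_trend <= 1))
  high <- grs_association(co, prof, "unweighted", "high_vs_rest")
  expect_equal(nrow(high), 1)
  per <- grs_association(co, prof, "unweighted", "per_unit")
  expect_true(per$or_adjusted > 0)
})

test_that("heterogeneity Z follows the closed form and null calibration", {
  expect_equal(heterogeneity_z(log(2), 0.1, 0, 0.1),
               log(2) / (0.1 * sqrt(2)))
  # identical coefficients give Z = 0, p = 1
  expect_equal(heterogeneity_z(0.5, 0.2, 0.5, 0.2), 0)
})

test_that("stratified_grs shares cutpoints across strata and reports Z", {
  co <- small_cohort(500, 500, seed = 37)
  prof <- compute_grs(co, study_weights())
  res <- stratified_grs(co, prof, stratify = "sex", score = "unweighted")
  expect_equal(sort(res$strata$stratum), sort(c("boy", "girl")))
  expect_equal(nrow(res$heterogeneity), 1)
  expect_true(res$heterogeneity$p > 0 & res$heterogeneity$p <= 1)
  # three age strata: pairwise Z plus a Cochran-Q
  res3 <- stratified_grs(co, prof, stratify = "age_group", score = "unweighted")
  expect_equal(nrow(res3$heterogeneity), 2)
  expect_true(!is.null(attr(res3$heterogeneity, "cochran_q")))
})
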