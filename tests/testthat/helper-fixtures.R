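# Shared fixtures and independent oracles.

# Tiny deterministic cohort with explicit dosages, no covariates.
toy_cohort <- function() {
  tibble::tibble(
    sample_id = sprintf("S%02d", 1:12),
    status = rep(c(1L, 0L), each = 6),
    v1 = c(0L, 1L, 2L, 1L, 2L, 2L, 0L, 0L, 1L, 0L, 1L, 2L),
    v2 = c(2L, 2L, 1L, 1L, 0L, 1L, 0L, 1L, 0L, 0L, 2L, 1L)
  )
}

# A small covariate-bearing cohort drawn from the null generator.
small_cohort <- function(n_cases = 150, n_controls = 160, seed = 11, ...) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls, seed = seed, ...)
  simulate_cohort(cfg, n_pool = max(4000, 12 * (n_cases + n_controls)))
}

# Study-score weights: the four component variants with their fixed published
# per-allele coefficients.
study_weights <- function() {
  default_sim_variants()[1:4, c("variant_id", "ref_allele", "alt_allele",
                                "risk_allele", "beta")]
}

# Brute-force HWE permutation oracle: shuffle the pooled alleles explicitly.
hwe_perm_brute <- function(dosages, B, seed) {
  d <- dosages[!is.na(dosages)]
  n <- length(d)
  n_alt <- sum(d)
  alleles <- c(rep(1L, n_alt), rep(0L, 2L * n - n_alt))
  stat <- function(cts) {
    p <- (2 * cts[1] + cts[2]) / (2 * n)
    ex <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    sum((cts - ex)^2 / ex)
  }
  obs <- stat(tabulate(d + 1L, 3L))
  set.seed(seed)
  hits <- 0L
  for (b in seq_len(B)) {
    s <- sample(alleles)
    perm <- s[seq_len(n)] + s[n + seq_len(n)]
    if (stat(tabulate(perm + 1L, 3L)) >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (B + 1)
}

# Exhaustive best-split oracle: plain loops over every variant and every
# nonempty proper subset of its observed categories (both orientations), with
# the same majority-branch missing rule and tie-breaking as the contract.
best_split_brute <- function(status, dosages, candidates, min_child,
                             unit = "samples") {
  n <- length(status)
  gini0 <- function(nc, nk) {
    p <- nc / (nc + nk)
    1 - p^2 - (1 - p)^2
  }
  g_parent <- gini0(sum(status == 1), sum(status == 0))
  best <- NULL
  for (v in candidates) {
    d <- dosages[[v]]
    cats <- sort(unique(d[!is.na(d)]))
    if (length(cats) < 2) next
    all_subs <- list()
    for (m in 1:(2^length(cats) - 2)) {
      s <- cats[as.logical(bitwAnd(m, 2^(seq_along(cats) - 1)))]
      if (cats[1] %in% s) all_subs <- c(all_subs, list(s))  # canonical form
    }
    for (ls in all_subs) {
      lk <- !is.na(d) & d %in% ls
      rk <- !is.na(d) & !(d %in% ls)
      maj_left <- sum(lk) >= sum(rk)
      left <- lk | (is.na(d) & maj_left)
      size <- function(idx) if (unit == "samples") sum(idx) else sum(status[idx] == 1)
      if (size(left) < min_child || size(!left) < min_child) next
      gl <- gini0(sum(status[left] == 1), sum(status[left] == 0))
      gr <- gini0(sum(status[!left] == 1), sum(status[!left] == 0))
      dec <- g_parent - (sum(left) * gl + sum(!left) * gr) / n
      if (dec <= 1e-12) next
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(variant = v, left_set = ls, decrease = dec)
      }
    }
  }
  best
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
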