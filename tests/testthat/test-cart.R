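# Classification-tree screening: Gini arithmetic, exhaustive splitting,
# growth, cross-validation, terminal-node risk.

test_that("gini matches the closed form", {
  expect_equal(gini(50, 50), 0.5)
  expect_equal(gini(100, 0), 0)
  expect_equal(gini(569, 431), 1 - 0.569^2 - 0.431^2)
  expect_error(gini(0, 0), "empty")
})

test_that("best_split equals the exhaustive-enumeration oracle", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(60:200, 1)
    status <- rbinom(n, 1, 0.5)
    dosages <- tibble::tibble(
      v1 = rbinom(n, 2, runif(1, 0.2, 0.5)),
      v2 = rbinom(n, 2, runif(1, 0.2, 0.5)),
      v3 = rbinom(n, 2, runif(1, 0.2, 0.5))
    )
    # sprinkle missingness to exercise majority routing
    dosages$v2[sample(n, 3)] <- NA
    got <- best_split(status, dosages, c("v1", "v2", "v3"), min_child = 10)
    want <- best_split_brute(status, dosages, c("v1", "v2", "v3"), min_child = 10)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$variant, want$variant)
      expect_equal(got$left_set, want$left_set)
      expect_equal(got$decrease, want$decrease)
    }
  }
})

test_that("a split yielding two pure children is chosen with maximal decrease", {
  status <- rep(c(1L, 0L), each = 60)
  dosages <- tibble::tibble(v1 = rep(c(0L, 2L), each = 60))
  sp <- best_split(status, dosages, "v1", min_child = 10)
  expect_equal(sp$variant, "v1")
  expect_equal(sp$decrease, gini(60, 60))
  # size constraint: no admissible split for a small node
  expect_null(best_split(status[1:80], dosages[1:80, , drop = FALSE], "v1",
                         min_child = 50))
})

test_that("grow_tree handles pure and perfectly predictive cohorts", {
  pure <- tibble::tibble(sample_id = as.character(1:200),
                         status = rep(1L, 200), v1 = rbinom(200, 2, 0.3))
  t1 <- grow_tree(pure, "v1")
  expect_equal(nrow(t1$nodes), 1)
  expect_true(t1$nodes$is_terminal[1])

  set.seed(24)
  d <- rbinom(400, 2, 0.4)
  perfect <- tibble::tibble(sample_id = as.character(1:400),
                            status = as.integer(d >= 1), v1 = d)
  t2 <- grow_tree(perfect, "v1")
  expect_equal(sum(t2$nodes$is_terminal), 2)
  expect_equal(t2$nodes$split_variant[1], "v1")
  expect_equal(cross_validate(perfect, "v1", seed = 1), 0)
})

test_that("counts are conserved and decreases non-negative along every split", {
  co <- small_cohort(250, 250, seed = 25)
  tree <- grow_tree(co, default_sim_variants()$variant_id,
                    min_parent = 60, min_child = 25)
  internal <- tree$nodes[!tree$nodes$is_terminal, ]
  for (i in seq_len(nrow(internal))) {
    l <- tree$nodes[tree$nodes$node_id == internal$left_child[i], ]
    r <- tree$nodes[tree$nodes$node_id == internal$right_child[i], ]
    expect_equal(l$n_cases + r$n_cases, internal$n_cases[i])
    expect_equal(l$n_controls + r$n_controls, internal$n_controls[i])
    expect_gt(internal$decrease[i], 0)
  }
})

test_that("tree growth is invariant to sample row order", {
  co <- small_cohort(150, 150, seed = 26)
  tree1 <- grow_tree(co, default_sim_variants()$variant_id,
                     min_parent = 60, min_child = 25)
  set.seed(1)
  shuffled <- co[sample(nrow(co)), ]
  tree2 <- grow_tree(shuffled, default_sim_variants()$variant_id,
                     min_parent = 60, min_child = 25)
  expect_identical(as.list(tidy(tree1)), as.list(tidy(tree2)))
})

test_that("interacting variants surface on the root path", {
  # status driven by a two-variant interaction: both variants should appear
  # on the path to the highest-risk terminal node in most seeds
  hit <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    n <- 1200
    v1 <- rbinom(n, 2, 0.35); v2 <- rbinom(n, 2, 0.35)
    v3 <- rbinom(n, 2, 0.35)
    y <- rbinom(n, 1, plogis(-0.8 + 1.4 * (v1 >= 1 & v2 >= 1)))
    co <- tibble::tibble(sample_id = as.character(1:n), status = y,
                         v1 = v1, v2 = v2, v3 = v3)
    tree <- grow_tree(co, c("v1", "v2", "v3"))
    used <- unique(stats::na.omit(tree$nodes$split_variant))
    if (all(c("v1", "v2") %in% used)) hit <- hit + 1
  }
  expect_gte(hit, 9)
})

test_that("cross-validation is deterministic and near 0.5 on pure noise", {
  set.seed(27)
  n <- 1000
  co <- tibble::tibble(
    sample_id = as.character(1:n),
    status = rep(c(0L, 1L), each = n / 2),
    v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4)
  )
  e1 <- cross_validate(co, c("v1", "v2"), seed = 5)
  e2 <- cross_validate(co, c("v1", "v2"), seed = 5)
  expect_identical(e1, e2)
  expect_lt(abs(e1 - 0.5), 0.06)
})

test_that("terminal-node ORs are referenced to the lowest-risk node", {
  co <- small_cohort(300, 300, seed = 28)
  tree <- grow_tree(co, default_sim_variants()$variant_id,
                    min_parent = 80, min_child = 35)
  res <- terminal_node_or(tree, co)
  expect_equal(sum(res$reference), 1)
  expect_equal(res$or[res$reference], 1)
  expect_equal(min(res$case_proportion), res$case_proportion[res$reference])
  expect_equal(sum(res$n_cases + res$n_controls), nrow(co))
})
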