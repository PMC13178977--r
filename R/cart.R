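# From-scratch binary classification tree over genotype predictors: Gini
# splitting with exhaustive enumeration of genotype-category subsets,
# node-size constraints, stratified cross-validation, and terminal-node risk
# estimation against the lowest-risk node.

#' Gini impurity of a case/control node
#'
#' \eqn{1 - p^2 - (1-p)^2} with `p` the case proportion.
#'
#' @param n_cases,n_controls Non-negative counts; their sum must be positive.
#' @return Impurity in `[0, 0.5]`.
#' @export
gini <- function(n_cases, n_controls) {
  n <- n_cases + n_controls
  if (n <= 0) abort("empty node")
  p <- n_cases / n
  1 - p^2 - (1 - p)^2
}

# Enumerate the proper nonempty genotype-category subsets of `cats` up to
# complement symmetry: every subset containing the smallest category.
left_subsets <- function(cats) {
  cats <- sort(cats)
  if (length(cats) < 2) return(list())
  rest <- cats[-1]
  subs <- list(cats[1])
  if (length(rest) == 2) {
    subs <- c(subs, list(c(cats[1], rest[1])), list(c(cats[1], rest[2])))
  }
  subs
}

#' Best Gini split of a node
#'
#' Evaluates every candidate variant and every nonempty proper subset of its
#' observed genotype categories (up to complement symmetry) as the left
#' branch, and returns the split maximising the Gini decrease subject to both
#' children containing at least `min_child` units. Missing genotypes at the
#' split variant follow the majority branch. Ties are broken by candidate
#' order, then by lexicographically smallest left subset.
#'
#' @param status 0/1 vector for the samples at the node.
#' @param dosages Tibble/data frame of dosage columns for the same samples.
#' @param candidates Character vector of candidate variant columns.
#' @param min_child Minimum child size.
#' @param unit `"samples"` (default) or `"cases"`: what the size constraints
#'   count.
#' @return `NULL` if no admissible split, else a list with `variant`,
#'   `left_set`, `majority_left`, `decrease`, and the left/right index
#'   vectors.
#' @export
best_split <- function(status, dosages, candidates, min_child = 50L,
                       unit = c("samples", "cases")) {
  unit <- match.arg(unit)
  n <- length(status)
  g_parent <- gini(sum(status == 1), sum(status == 0))
  best <- NULL
  for (v in candidates) {
    d <- dosages[[v]]
    cats <- sort(unique(d[!is.na(d)]))
    for (ls in left_subsets(cats)) {
      left_known <- !is.na(d) & d %in% ls
      right_known <- !is.na(d) & !(d %in% ls)
      majority_left <- sum(left_known) >= sum(right_known)
      left <- left_known | (is.na(d) & majority_left)
      right <- !left
      size <- function(idx) {
        if (unit == "samples") sum(idx) else sum(status[idx] == 1)
      }
      if (size(left) < min_child || size(right) < min_child) next
      gl <- gini(sum(status[left] == 1), sum(status[left] == 0))
      gr <- gini(sum(status[right] == 1), sum(status[right] == 0))
      dec <- g_parent - (sum(left) * gl + sum(right) * gr) / n
      if (dec <= 1e-12) next
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(
          variant = v, left_set = ls, majority_left = majority_left,
          decrease = dec, left = which(left), right = which(right)
        )
      }
    }
  }
  best
}

#' Grow a classification tree
#'
#' Recursive partitioning with [best_split()] until no node satisfies the
#' parent-size constraint or yields a positive Gini decrease. Node ids follow
#' the heap convention (root 1, children of `k` are `2k`, `2k+1`).
#'
#' @param cohort Cohort tibble with `status`.
#' @param variants Candidate variant columns (character vector or variant
#'   tibble).
#' @param min_parent Minimum node size to attempt a split.
#' @param min_child Minimum size of each child.
#' @param unit What the size constraints count (`"samples"` or `"cases"`).
#' @return A `grsxe_tree`: list with `nodes` (tibble), `params`, and the
#'   per-sample terminal assignment in `node_of`.
#' @export
grow_tree <- function(cohort, variants, min_parent = 100L, min_child = 50L,
                      unit = c("samples", "cases")) {
  unit <- match.arg(unit)
  ids <- variant_cols(cohort, variants)
  status <- check_status(cohort$status)
  n <- length(status)
  if (n == 0) abort("empty cohort")

  nodes <- list()
  node_of <- integer(n)
  queue <- list(list(id = 1L, idx = seq_len(n)))
  while (length(queue) > 0) {
    nd <- queue[[1]]; queue <- queue[-1]
    st <- status[nd$idx]
    nc <- sum(st == 1); nk <- sum(st == 0)
    g <- gini(nc, nk)
    size <- if (unit == "samples") length(nd$idx) else nc
    sp <- NULL
    if (size >= min_parent && g > 0) {
      sp <- best_split(st, cohort[nd$idx, ids, drop = FALSE], ids,
                       min_child = min_child, unit = unit)
    }
    if (is.null(sp)) {
      nodes[[length(nodes) + 1]] <- tibble(
        node_id = nd$id, n_cases = nc, n_controls = nk, gini = g,
        is_terminal = TRUE, split_variant = NA_character_,
        left_set = list(NULL), majority_left = NA, decrease = NA_real_,
        left_child = NA_integer_, right_child = NA_integer_
      )
      node_of[nd$idx] <- nd$id
    } else {
      nodes[[length(nodes) + 1]] <- tibble(
        node_id = nd$id, n_cases = nc, n_controls = nk, gini = g,
        is_terminal = FALSE, split_variant = sp$variant,
        left_set = list(sp$left_set), majority_left = sp$majority_left,
        decrease = sp$decrease,
        left_child = 2L * nd$id, right_child = 2L * nd$id + 1L
      )
      queue <- c(queue, list(
        list(id = 2L * nd$id, idx = nd$idx[sp$left]),
        list(id = 2L * nd$id + 1L, idx = nd$idx[sp$right])
      ))
    }
  }
  nodes <- dplyr::arrange(dplyr::bind_rows(nodes), .data$node_id)
  structure(
    list(
      nodes = nodes, node_of = node_of,
      params = list(min_parent = min_parent, min_child = min_child, unit = unit)
    ),
    class = "grsxe_tree"
  )
}

#' @export
print.grsxe_tree <- function(x, ...) {
  nt <- sum(x$nodes$is_terminal)
  cat(sprintf("<grsxe_tree> %d node(s), %d terminal\n", nrow(x$nodes), nt))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a grown tree
#'
#' @param x A `grsxe_tree`.
#' @param ... Unused.
#' @return One row per node with counts, impurity, split definition (left
#'   subset as a "0/1" style string) and child ids.
#' @export
tidy.grsxe_tree <- function(x, ...) {
  out <- x$nodes
  out$left_set <- vapply(out$left_set, function(s) {
    if (is.null(s)) NA_character_ else paste(s, collapse = ",")
  }, character(1))
  out$case_proportion <- out$n_cases / (out$n_cases + out$n_controls)
  out
}

#' @rdname tidy.grsxe_tree
#' @export
glance.grsxe_tree <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_terminal = sum(x$nodes$is_terminal),
    depth = max(floor(log2(x$nodes$node_id))),
    n = x$nodes$n_cases[1] + x$nodes$n_controls[1]
  )
}

# Route samples down a tree; returns the terminal node id for each row.
route_samples <- function(tree, cohort) {
  nodes <- tree$nodes
  n <- nrow(cohort)
  out <- integer(n)
  assign_node <- function(idx, id) {
    row <- nodes[nodes$node_id == id, ]
    if (row$is_terminal) {
      out[idx] <<- id
      return(invisible())
    }
    d <- cohort[[row$split_variant]][idx]
    ls <- row$left_set[[1]]
    left <- ifelse(is.na(d), row$majority_left, d %in% ls)
    if (any(left)) assign_node(idx[left], row$left_child)
    if (any(!left)) assign_node(idx[!left], row$right_child)
  }
  if (n > 0) assign_node(seq_len(n), 1L)
  out
}

#' Stratified k-fold cross-validated misclassification rate
#'
#' Folds are stratified by status. Per fold a tree is grown on the remaining
#' folds and held-out samples are classified by the majority status of their
#' terminal node (overall training majority on a tie or when no split was
#' possible).
#'
#' @inheritParams grow_tree
#' @param k Number of folds.
#' @param seed Integer seed controlling the fold assignment.
#' @return The average held-out misclassification rate.
#' @export
cross_validate <- function(cohort, variants, k = 10L, seed = 1L,
                           min_parent = 100L, min_child = 50L,
                           unit = c("samples", "cases")) {
  unit <- match.arg(unit)
  if (k < 2 || nrow(cohort) < k) abort("need k >= 2 and at least k samples")
  status <- check_status(cohort$status)
  withr_seed(seed, {
    fold <- integer(length(status))
    for (s in c(0L, 1L)) {
      idx <- which(status == s)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    wrong <- 0L
    for (f in seq_len(k)) {
      train <- cohort[fold != f, , drop = FALSE]
      test <- cohort[fold == f, , drop = FALSE]
      tree <- grow_tree(train, variants, min_parent = min_parent,
                        min_child = min_child, unit = unit)
      maj <- as.integer(mean(train$status) >= 0.5)
      nd <- route_samples(tree, test)
      pred <- vapply(nd, function(id) {
        row <- tree$nodes[tree$nodes$node_id == id, ]
        if (row$n_cases == row$n_controls) maj else as.integer(row$n_cases > row$n_controls)
      }, integer(1))
      wrong <- wrong + sum(pred != test$status)
    }
    wrong / nrow(cohort)
  })
}

#' Adjusted odds ratios of terminal nodes
#'
#' The terminal node with the lowest case proportion is the reference (lowest
#' node id on a tie); one adjusted logistic model with terminal-node
#' membership indicators plus the standard covariates gives each node's OR.
#'
#' @param tree A `grsxe_tree` grown on `cohort`.
#' @param cohort The cohort the tree was grown on.
#' @param covariates Adjustment covariates.
#' @return Tibble with one row per terminal node: counts, case proportion,
#'   `or`, `conf.low`, `conf.high`, `p.value` (reference row has OR 1 and NA
#'   inference).
#' @export
terminal_node_or <- function(tree, cohort,
                             covariates = c("age_group", "sex", "maternal_edu",
                                            "paternal_edu", "income")) {
  term <- dplyr::filter(tree$nodes, .data$is_terminal)
  term$case_proportion <- term$n_cases / (term$n_cases + term$n_controls)
  ref <- term$node_id[order(term$case_proportion, term$node_id)][1]
  nd <- route_samples(tree, cohort)
  others <- setdiff(term$node_id, ref)
  ind <- vapply(others, function(id) as.numeric(nd == id), numeric(nrow(cohort)))
  colnames(ind) <- paste0("node", others)
  X <- cbind(ind, covariate_matrix(cohort, covariates))
  keep <- stats::complete.cases(X)
  fit <- fit_logistic(X[keep, , drop = FALSE], cohort$status[keep])
  td <- tidy(fit)
  out <- term %>%
    dplyr::select("node_id", "n_cases", "n_controls", "case_proportion") %>%
    dplyr::mutate(
      reference = .data$node_id == ref,
      or = NA_real_, conf.low = NA_real_, conf.high = NA_real_, p.value = NA_real_
    )
  for (i in seq_along(others)) {
    r <- td[td$term == paste0("node", others[i]), ]
    j <- which(out$node_id == others[i])
    out$or[j] <- r$or; out$conf.low[j] <- r$conf.low
    out$conf.high[j] <- r$conf.high; out$p.value[j] <- r$p.value
  }
  out$or[out$reference] <- 1
  attr(out, "fit") <- fit
  out
}
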