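# ggplot2 result-type plots.

#' Forest plot of odds ratios
#'
#' Generic helper used by the autoplot methods: point estimates with CI bars
#' on a log OR axis.
#'
#' @param data Tibble with `label`, `or`, `conf.low`, `conf.high`.
#' @return A ggplot.
#' @export
plot_or_forest <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI, log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.grsxe_crossover <- function(object, ...) {
  data <- object$estimates %>%
    dplyr::mutate(label = factor(.data$cell, levels = c("or10", "or01", "or11"),
                                 labels = c("High GRS only", "Exposed only",
                                            "High GRS + exposed")))
  plot_or_forest(data) +
    ggplot2::labs(title = paste0("Joint effects: GRS x ", object$exposure))
}

#' @export
autoplot.grsxe_tree <- function(object, ...) {
  nodes <- tidy(object)
  nodes$depth <- floor(log2(nodes$node_id))
  # heap coordinates: position within the level
  nodes$x <- (nodes$node_id - 2^nodes$depth + 0.5) / 2^nodes$depth
  edges <- nodes %>%
    dplyr::filter(!.data$is_terminal) %>%
    dplyr::select("node_id", "x", "depth", "left_child", "right_child") %>%
    tidyr::pivot_longer(c("left_child", "right_child"), values_to = "child") %>%
    dplyr::inner_join(
      dplyr::select(nodes, child = "node_id", xend = "x", depth_end = "depth"),
      by = "child"
    )
  lab <- ifelse(
    nodes$is_terminal,
    sprintf("node %d\n%d/%d (%.1f%%)", nodes$node_id, nodes$n_cases,
            nodes$n_controls, 100 * nodes$case_proportion),
    sprintf("%s in {%s}", nodes$split_variant, nodes$left_set)
  )
  ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = -.data$depth)) +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = -.data$depth,
                   xend = .data$xend, yend = -.data$depth_end)
    ) +
    ggplot2::geom_label(ggplot2::aes(label = lab), size = 2.6) +
    ggplot2::theme_void()
}

#' Distribution of genetic risk scores by status
#'
#' @param profiles Tibble from [compute_grs()].
#' @param score `"unweighted"` or `"weighted"`.
#' @return A ggplot.
#' @export
plot_grs_distribution <- function(profiles, score = c("unweighted", "weighted")) {
  score <- match.arg(score)
  data <- profiles %>%
    dplyr::filter(.data$complete) %>%
    dplyr::mutate(group = ifelse(.data$status == 1, "cases", "controls"))
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[score]], fill = .data$group)) +
    ggplot2::geom_histogram(position = "dodge", bins = 15) +
    ggplot2::labs(x = paste(score, "GRS"), y = "samples", fill = NULL) +
    ggplot2::theme_minimal()
}
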