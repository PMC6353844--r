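# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot node-probability time courses of an ensemble
#'
#' @param object an `ensemble_result`.
#' @param nodes nodes to show (default: the read-outs, else all).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ensemble_result <- function(object, nodes = NULL, ...) {
  if (is.null(nodes)) {
    nodes <- if (length(object$outputs)) object$outputs else object$nodes
  }
  d <- tidy(object) %>% dplyr::filter(.data$node %in% nodes)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$probability,
                                  colour = .data$node)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$probability - 2 * .data$std_error, 0),
                   ymax = pmin(.data$probability + 2 * .data$std_error, 1),
                   fill = .data$node),
      alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "activation probability",
                  colour = "node", fill = "node") +
    ggplot2::theme_minimal()
}

#' Density of cohort phenotype probabilities
#'
#' One panel per phenotype; the dashed line marks the wild-type
#' (unpersonalized) model probability.
#'
#' @param object a `phenotype_table` from [simulate_cohort()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.phenotype_table <- function(object, ...) {
  wt <- attr(object, "wild_type")
  d <- tidyr::pivot_longer(tibble::as_tibble(object), -"patient",
                           names_to = "phenotype", values_to = "probability")
  wt_d <- tibble::tibble(phenotype = names(wt), probability = unname(wt))
  ggplot2::ggplot(d, ggplot2::aes(.data$probability)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(data = wt_d,
                        ggplot2::aes(xintercept = .data$probability),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~phenotype, scales = "free_y") +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "asymptotic phenotype probability", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a gene's distribution fit
#'
#' Histogram of the cohort values with the fitted transform overlaid on a
#' secondary axis (normalized value in `[0, 1]`).
#'
#' @param values the gene's expression values.
#' @param fit a `gene_fit` from [classify_gene()].
#' @param bins histogram bins.
#' @return a ggplot.
#' @export
plot_gene_fit <- function(values, fit, bins = 50) {
  grid <- seq(min(values), max(values), length.out = 200)
  norm <- normalize_gene(grid, fit)
  ggplot2::ggplot(tibble::tibble(x = values), ggplot2::aes(.data$x)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$ncount)),
                            bins = bins, fill = "grey75") +
    ggplot2::geom_line(data = tibble::tibble(x = grid, y = norm),
                       ggplot2::aes(.data$x, .data$y), colour = "firebrick") +
    ggplot2::labs(x = "expression", y = "scaled count / normalized value",
                  title = sprintf("category: %s", fit$category)) +
    ggplot2::theme_minimal()
}
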