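# ggplot2 displays for analysis tables.

#' Plot an analysis table
#'
#' Point estimates with Wald confidence intervals per technique, faceted by
#' item (comparative stage) or by game (aggregate and individual stages)
#' and metric.
#'
#' @param object An `rrt_analysis` tibble from [comparative_analysis()],
#'   [aggregate_validation()] or [individual_validation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rrt_analysis
#' @export
autoplot.rrt_analysis <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$technique, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)) +
    ggplot2::labs(x = NULL, y = "Estimate (proportion)") +
    ggplot2::theme_minimal()
  if (attr(object, "stage") == "comparative") {
    p + ggplot2::facet_grid(item ~ metric)
  } else {
    p + ggplot2::facet_grid(game ~ metric)
  }
}

#' Plot the individual-level validation summary of a results object
#'
#' @param x An `rrt_results` object from [run_analysis()].
#' @param stage Which table to plot (`"individual"`, `"comparative"`,
#'   `"aggregate"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_validation <- function(x, stage = c("individual", "comparative", "aggregate"),
                            ...) {
  stopifnot(inherits(x, "rrt_results"))
  stage <- match.arg(stage)
  autoplot(x[[stage]])
}
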