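# ggplot2 views of the result objects.

#' @describeIn cea_frontier Cost-effectiveness frontier plot: strategies on
#'   the (QALY, cost) plane, non-dominated entries joined by the frontier.
#' @param object,x an `asd_cea` object.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.asd_cea <- function(object, ...) {
  tab <- object$summaries
  alive <- tab[tab$dominance == "none", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$expected_qalys,
                                    y = .data$expected_cost)) +
    ggplot2::geom_line(data = alive, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$dominance), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "Expected discounted QALYs",
                  y = "Expected lifetime cost (USD)",
                  shape = "Dominance") +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' Horizontal bars spanning the ICERs obtained at each parameter's low and
#' high value, widest at the top, with the base-case ICER as a vertical
#' reference line. Infinite ICERs (a comparison with no QALY difference)
#' are clipped to the plotted range.
#'
#' @param object an `asd_tornado` from [tornado()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.asd_tornado <- function(object, ...) {
  tab <- tidy(object)
  base <- attr(object, "base_icer")
  finite <- c(tab$icer_at_low, tab$icer_at_high, base)
  finite <- finite[is.finite(finite)]
  clip <- max(abs(finite)) * 1.2
  tab <- mutate(tab,
    lo = pmin(pmax(pmin(.data$icer_at_low, .data$icer_at_high), -clip), clip),
    hi = pmin(pmax(pmax(.data$icer_at_low, .data$icer_at_high), -clip), clip),
    parameter = factor(.data$parameter, levels = rev(.data$parameter))
  )
  ggplot2::ggplot(tab, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Scatter of the PSA's incremental (QALY, cost) pairs with the
#' willingness-to-pay thresholds drawn as lines through the origin.
#'
#' @param object an `asd_psa` from [run_psa()].
#' @param wtp thresholds to draw (default `c(50000, 100000)`).
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.asd_psa <- function(object, wtp = c(50000, 100000), ...) {
  tab <- tidy(object)
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$d_qalys,
                                         y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)") +
    ggplot2::theme_minimal()
  for (w in wtp) {
    p <- p + ggplot2::geom_abline(slope = w, intercept = 0, linetype = 2)
  }
  p
}
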