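# ggplot2 views of the main result types.

#' Plot RNA element class composition
#'
#' Bar chart of element counts per class for a discovery result.
#'
#' @param object An `re_discovery`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.re_discovery <- function(object, ...) {
  df <- object$elements |>
    dplyr::count(.data$re_class) |>
    mutate(re_class = factor(
      .data$re_class, levels = c("Exonic", "Intronic", "NearExon", "Orphan")
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$re_class, y = .data$n,
                                   fill = .data$re_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL, y = "RNA elements",
      title = sprintf("RNA elements at μ = %.2f RPM", object$config$mu)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a PPV parameter grid
#'
#' PPV against the expression threshold, one line per discovery
#' stringency mu.
#'
#' @param object A `ppv_grid` from [ppv_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ppv_grid <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$threshold, y = .data$ppv,
                 colour = factor(.data$mu), group = .data$mu)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Expression threshold (RPKM)", y = "PPV",
      colour = "μ (RPM)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot repeat enrichment results
#'
#' Observed versus expected expressed-element counts per repeat, with
#' retained repeats highlighted.
#'
#' @param object An `re_enrichment` from [test_repeat_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.re_enrichment <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$expected, y = .data$k,
                 colour = .data$direction, shape = .data$retained)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Expected expressed elements", y = "Observed expressed elements",
      colour = NULL, shape = "retained"
    ) +
    ggplot2::theme_minimal()
}
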