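#' Forest plot of derived posterior quantities
#'
#' Caterpillar display of level-specific correlations, repeatabilities or
#' survival gradients: posterior mode with 95% HPD bars, faceted by
#' hierarchical level where applicable.
#'
#' @param object A `tv_derived` tibble from [tv_correlations()],
#'   [tv_repeatability()] or [tv_survival_gradients()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tv_derived <- function(object, ...) {
  quantity <- attr(object, "quantity") %||% "quantity"
  d <- as_tibble(object)
  d$label <- if (all(c("trait_1", "trait_2") %in% names(d))) {
    paste(d$trait_1, d$trait_2, sep = " ~ ")
  } else if ("predictor" %in% names(d)) {
    d$predictor
  } else {
    d$trait
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.15) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 2) +
    ggplot2::labs(x = paste0("posterior mode of ", quantity,
                             " (95% HPD)"), y = NULL) +
    ggplot2::theme_minimal()
  if ("level" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~level)
  }
  p
}

#' Trace plot of stored chains from a fit
#'
#' @param object A `tv_fit`.
#' @param pars Regular expression selecting fixed-effect columns (default all).
#' @param ... Unused.
#' @return A ggplot object showing the stored (thinned) fixed-effect chains.
#' @export
autoplot.tv_fit <- function(object, pars = ".", ...) {
  b <- object$draws$beta
  keep <- grep(pars, colnames(b), value = TRUE)
  d <- as_tibble(b[, keep, drop = FALSE]) |>
    dplyr::mutate(draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-"draw", names_to = "term", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$draw, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "stored draw", y = NULL) +
    ggplot2::theme_minimal()
}
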