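#' Plot degradation curves
#'
#' @param sims A `lysis_sim`, a list of them, or a data frame with
#'   `time_s`, `degraded_fraction` and optionally `scenario`/`replicate`
#'   columns.
#' @return A ggplot.
#' @export
plot_degradation <- function(sims) {
  df <- collect_records(sims)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60,
                                        y = .data$degraded_fraction))
  if ("scenario" %in% names(df)) {
    p <- p + ggplot2::aes(colour = .data$scenario)
  }
  if ("replicate" %in% names(df)) {
    p <- p + ggplot2::aes(group = interaction(
      .data$replicate, if ("scenario" %in% names(df)) .data$scenario else 1))
  }
  p + ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "time (min)", y = "fraction of clot degraded")
}

collect_records <- function(sims) {
  if (inherits(sims, "lysis_sim")) {
    df <- sims$records
    df$scenario <- sims$spec$name
    return(df)
  }
  if (is.data.frame(sims)) return(sims)
  purrr::imap_dfr(sims, function(s, k) {
    df <- s$records
    df$scenario <- s$spec$name
    df$replicate <- if (!is.null(attr(s, "replicate"))) attr(s, "replicate") else k
    df
  })
}

#' Plot a pore-expansion series
#'
#' @param expansion Output of [pore_expansion()], optionally row-bound over
#'   scenarios with a `scenario` column.
#' @return A ggplot of percent pore change against degradation checkpoint.
#' @export
plot_pore_expansion <- function(expansion) {
  p <- ggplot2::ggplot(expansion, ggplot2::aes(x = 100 * .data$target,
                                               y = .data$percent_change))
  if ("scenario" %in% names(expansion)) {
    p <- p + ggplot2::aes(colour = .data$scenario, group = .data$scenario)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 132, linetype = "dotted") +
    ggplot2::labs(x = "degradation checkpoint (%)",
                  y = "pore size change vs intact (%)")
}

#' Plot turbidity curves
#'
#' @param curves Output of [read_plate_export()] or [synth_turbidity()].
#' @param normalized Plot the fraction-of-clot normalization instead of
#'   background-subtracted OD.
#' @return A ggplot.
#' @export
plot_turbidity <- function(curves, normalized = TRUE) {
  yvar <- if (normalized) "od_frac" else "od_bg"
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time_s / 60,
                                            y = .data[[yvar]]))
  if ("well" %in% names(curves)) {
    p <- p + ggplot2::aes(colour = .data$well)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)",
                  y = if (normalized) "fraction of clot" else "OD (405 nm)")
}

#' @export
autoplot.lysis_sim <- function(object, ...) plot_degradation(object)

#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(min(object$data$x), max(object$data$x),
                                 length.out = 100))
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "fibrinogen (mg/mL)", y = "degradation rate (frac/min)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
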