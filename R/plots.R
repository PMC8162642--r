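#' Plot a two-channel trace
#'
#' Points for the observed MS2 (mCherry) and PP7 (eGFP) signals of one cell.
#'
#' @param trace A single-cell trace tibble.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  long <- tidyr::pivot_longer(trace, c("ms2_au", "pp7_au"),
                              names_to = "channel", values_to = "au")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$au,
                                     colour = .data$channel)) +
    ggplot2::geom_point(size = 0.8, na.rm = TRUE) +
    ggplot2::scale_colour_manual(
      values = c(ms2_au = "#c23b22", pp7_au = "#2e8b57"),
      labels = c(ms2_au = "MS2 (mCherry)", pp7_au = "PP7 (eGFP)")) +
    ggplot2::labs(x = "time since mitosis (min)", y = "fluorescence (AU)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_trace Observed trace overlaid with the posterior-mean
#'   model prediction of a `tx_fit`.
#' @param object A `tx_fit` from [summarize_chain()].
#' @param ... Unused.
#' @export
autoplot.tx_fit <- function(object, ...) {
  trace <- attr(object, "trace")
  geom <- attr(object, "geom")
  p_hat <- attr(object, "params")
  if (is.null(trace) || is.null(p_hat)) {
    stop("this tx_fit does not carry its trace")
  }
  pred <- predict_traces(p_hat, geom, trace$time_min)
  pl <- tidyr::pivot_longer(pred, c("ms2_au", "pp7_au"),
                            names_to = "channel", values_to = "au")
  plot_trace(trace) +
    ggplot2::geom_line(data = pl, ggplot2::aes(.data$time_min, .data$au,
                                               colour = .data$channel),
                       linewidth = 0.7)
}

#' Trace plots of raw MCMC chains
#'
#' One panel per parameter, sample value against step; rapid wandering with
#' no drift indicates good mixing.
#'
#' @param object A `tx_chain` from [run_mcmc()].
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tx_chain <- function(object, parameters = NULL, ...) {
  m <- unclass(object)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  d <- as_tibble(m)
  d$step <- seq_len(nrow(d))
  long <- tidyr::pivot_longer(d, -"step", names_to = "parameter")
  if (!is.null(parameters)) {
    long <- dplyr::filter(long, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "#33527a") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "MCMC step", y = "parameter value") +
    ggplot2::theme_minimal()
}

#' Plot binned parameter profiles along the embryo
#'
#' Mean with standard-error ribbon against AP position, one facet per
#' parameter, from [bin_by_position()] output.
#'
#' @param binned Tibble from [bin_by_position()].
#' @return A ggplot object.
#' @export
plot_ap_profile <- function(binned) {
  ggplot2::ggplot(binned, ggplot2::aes(.data$bin_mid, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, fill = "#33527a") +
    ggplot2::geom_line(colour = "#33527a") +
    ggplot2::geom_point(size = 0.9, colour = "#33527a") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "anterior-posterior position (embryo fraction)",
                  y = "bin mean ± SEM") +
    ggplot2::theme_minimal()
}
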