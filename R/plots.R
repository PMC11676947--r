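#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_segment labs
#'   theme_minimal facet_wrap autoplot
NULL

#' Plot a single-cell voltage trace
#'
#' @param object a `trace_record`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.trace_record <- function(object, ...) {
  if (is.null(object$trace)) abort("trace was not recorded")
  ggplot(object$trace, aes(x = .data$t, y = .data$v)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = "membrane potential (mV)",
         title = object$params$label) +
    theme_minimal()
}

#' Plot a network spike raster
#'
#' @param object a `raster_record`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.raster_record <- function(object, ...) {
  ggplot(object$spikes, aes(x = .data$t, y = .data$id,
                            colour = .data$population)) +
    geom_point(shape = ".", alpha = 0.6) +
    labs(x = "time (ms)", y = "neuron", colour = NULL) +
    theme_minimal()
}

#' Plot a mean-field trajectory
#'
#' Population rates (and, on a separate facet, the adaptation currents)
#' against time.
#'
#' @param object an `mf_trajectory`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.mf_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("t", "nu_e", "nu_i", "w_e", "w_i")],
    -"t", names_to = "variable", values_to = "value")
  long$panel <- ifelse(long$variable %in% c("nu_e", "nu_i"),
                       "rate (Hz)", "adaptation (pA)")
  ggplot(long, aes(x = .data$t, y = .data$value, colour = .data$variable)) +
    geom_line() +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a protocol response curve
#'
#' @param object a `response_curve` tibble (first column is the scanned
#'   variable, second the response)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.response_curve <- function(object, ...) {
  xnm <- names(object)[1]
  ynm <- names(object)[2]
  ggplot(object, aes(x = .data[[xnm]], y = .data[[ynm]])) +
    geom_line() + geom_point() +
    labs(x = xnm, y = ynm) +
    theme_minimal()
}
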