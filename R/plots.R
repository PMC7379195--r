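#' ERP waveform as a long tibble
#'
#' @param erp An `erp_average`.
#' @return Tibble with `channel`, `time_ms`, `uv`.
#' @export
erp_to_tibble <- function(erp) {
  t_ms <- epoch_times(erp)
  tibble::tibble(
    channel = rep(erp$channels, each = length(t_ms)),
    time_ms = rep(t_ms, times = length(erp$channels)),
    uv = as.numeric(t(erp$data))
  )
}

#' Plot an ERP average
#'
#' One line per channel; negativity is plotted upward by ERP convention.
#'
#' @param object An `erp_average`.
#' @param channels Optional channel subset.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.erp_average <- function(object, channels = NULL, ...) {
  d <- erp_to_tibble(object)
  if (!is.null(channels)) d <- dplyr::filter(d, .data$channel %in% channels)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$uv,
                                  colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Time (ms)", y = "Amplitude (µV)",
                  title = object$selector) +
    ggplot2::theme_minimal()
}

#' Plot prior, likelihood, and posterior of a Bayes-factor analysis
#'
#' Shows the alternative-hypothesis prior, the t likelihood of the data,
#' and the resulting posterior over the effect, the standard way of
#' displaying an informed-prior Bayes factor.
#'
#' @param object A `bf_result`.
#' @param n_points Curve resolution.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bf_result <- function(object, n_points = 512, ...) {
  eff <- object$effect
  pr <- object$prior
  span <- switch(pr$family,
    uniform = c(pr$lower, pr$upper),
    point = pr$location + c(-1, 1),
    normal = pr$location + c(-4, 4) * pr$scale,
    half_normal = c(0, 4 * pr$scale)
  )
  lo <- min(span[1], eff$mean_diff - 4 * eff$se, object$null_point)
  hi <- max(span[2], eff$mean_diff + 4 * eff$se, object$null_point)
  theta <- seq(lo, hi, length.out = n_points)
  prior_d <- switch(pr$family,
    uniform = stats::dunif(theta, pr$lower, pr$upper),
    point = rep(0, n_points),
    normal = stats::dnorm(theta, pr$location, pr$scale),
    half_normal = ifelse(theta >= 0, 2 * stats::dnorm(theta, 0, pr$scale), 0)
  )
  lik <- effect_likelihood(eff)(theta)
  post <- prior_d * lik
  post <- post / (sum(post) * (theta[2] - theta[1]))
  d <- tibble::tibble(
    theta = rep(theta, 3),
    density = c(prior_d, lik, post),
    curve = rep(c("prior", "likelihood", "posterior"), each = n_points)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$theta, .data$density,
                                  colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$null_point, linetype = 2,
                        linewidth = 0.3) +
    ggplot2::labs(x = expression(theta), y = "Density",
                  subtitle = sprintf("BF01 = %.2f (%s)", object$bf01,
                                     object$evidence_label)) +
    ggplot2::theme_minimal()
}

#' Plot a tone sequence
#'
#' Tone frequency over trials, coloured by event role; a quick visual
#' check of the oddball, cascade, and no-repetition ordering rules.
#'
#' @param object A `tone_sequence`.
#' @param max_trials Show at most this many events from the start.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tone_sequence <- function(object, max_trials = 64, ...) {
  d <- utils::head(object, max_trials)
  ggplot2::ggplot(d, ggplot2::aes(.data$trial_index, .data$frequency_hz,
                                  colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.2) +
    ggplot2::labs(x = "Trial", y = "Frequency (Hz)",
                  title = paste(d$condition[1], "sequence")) +
    ggplot2::theme_minimal()
}
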