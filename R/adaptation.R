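#' Neural-adaptation parameters for the N1
#'
#' The N1 to a tone is attenuated when preceding tones are recent and
#' tonotopically close. The model aggregates the preceding tones of a
#' trial into a score `S` in `[0, 1]`:
#'
#'   S = sum_l w_l K(d_l) / sum_l w_l,   w_l = exp(-l / tau),
#'   K(d) = exp(-d^2 / (2 sigma^2)),
#'
#' where `l` is the lag in trials, `d_l` the log2-frequency distance in
#' octaves between the current tone and the tone at lag `l`, `tau` the
#' recency constant (`recency_tau_trials`) and `sigma` the tonotopic
#' kernel width (`tonotopic_sd_oct`). The N1 amplitude on that trial is
#' then `base_n1_uv * (1 - strength * S)`, so the gain lies in
#' `[1 - strength, 1]` and equals 1 for an empty history.
#'
#' @param base_n1_uv Unadapted N1 peak amplitude in microvolts (negative).
#' @param strength Maximal fractional N1 reduction, in `[0, 1]`.
#' @param tonotopic_sd_oct Gaussian kernel width over log2-frequency
#'   distance, in octaves.
#' @param recency_tau_trials Exponential decay constant of a preceding
#'   tone's contribution with lag, in trials.
#' @param history_len Number of preceding tones considered.
#' @return A list of class `"adaptation_params"`.
#' @export
adaptation_params <- function(base_n1_uv = -2.124, strength = 0.295,
                              tonotopic_sd_oct = 0.25,
                              recency_tau_trials = 0.8,
                              history_len = 10) {
  stopifnot(
    strength >= 0, strength <= 1,
    tonotopic_sd_oct > 0,
    recency_tau_trials > 0,
    history_len >= 1
  )
  structure(
    list(
      base_n1_uv = base_n1_uv, strength = strength,
      tonotopic_sd_oct = tonotopic_sd_oct,
      recency_tau_trials = recency_tau_trials,
      history_len = as.integer(history_len)
    ),
    class = "adaptation_params"
  )
}

#' Adaptation score and gain for a single tone
#'
#' `adaptation_score()` returns the normalized history aggregate `S` in
#' `[0, 1]` (see [adaptation_params()]); `adaptation_gain()` returns the
#' multiplicative N1 gain `1 - strength * S`.
#'
#' @param freq_hz Frequency of the current tone, Hz.
#' @param history_hz Frequencies of preceding tones, most recent first.
#'   May be empty (score 0, gain 1).
#' @param params An [adaptation_params()].
#' @return A scalar.
#' @export
adaptation_score <- function(freq_hz, history_hz, params = adaptation_params()) {
  history_hz <- utils::head(history_hz, params$history_len)
  if (length(history_hz) == 0) return(0)
  lag <- seq_along(history_hz)
  w <- exp(-lag / params$recency_tau_trials)
  d <- log2(history_hz / freq_hz)
  k <- exp(-d^2 / (2 * params$tonotopic_sd_oct^2))
  sum(w * k) / sum(w)
}

#' @rdname adaptation_score
#' @export
adaptation_gain <- function(freq_hz, history_hz, params = adaptation_params()) {
  1 - params$strength * adaptation_score(freq_hz, history_hz, params)
}

#' Adaptation scores for every event of a sequence
#'
#' Vectorized over a whole `tone_sequence`: the history of event `i` is
#' the `history_len` events preceding it in the block (warm-up tones
#' included, which is why warm-ups are simulated at all).
#'
#' @param seq A `tone_sequence` tibble (or any tibble with a
#'   `frequency_hz` column in presentation order).
#' @inheritParams adaptation_score
#' @return Numeric vector of scores, one per event, in `[0, 1]`.
#' @export
adaptation_scores <- function(seq, params = adaptation_params()) {
  f <- log2(seq$frequency_hz)
  n <- length(f)
  lags <- seq_len(params$history_len)
  w <- exp(-lags / params$recency_tau_trials)
  num <- numeric(n)
  den <- numeric(n)
  for (l in lags) {
    lagged <- c(rep(NA_real_, l), f[seq_len(n - l)])
    k <- exp(-(f - lagged)^2 / (2 * params$tonotopic_sd_oct^2))
    has <- !is.na(lagged)
    num[has] <- num[has] + w[l] * k[has]
    den[has] <- den[has] + w[l]
  }
  ifelse(den > 0, num / pmax(den, .Machine$double.eps), 0)
}
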