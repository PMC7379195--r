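#' Recording parameters for synthetic epochs
#'
#' @param fs_hz Sampling rate in Hz.
#' @param epoch_window_ms Epoch window relative to tone onset,
#'   `c(start, end)` in ms; must straddle 0.
#' @param channels Ordered channel labels. Channels listed in
#'   `mastoid_channels` receive each component scaled by its signed
#'   mastoid gain (polarity reversal under a nose reference); all other
#'   channels are treated as frontocentral and receive gain 1.
#' @param mastoid_channels Subset of `channels` acting as mastoid proxies.
#' @return A list of class `"recording_spec"`.
#' @export
recording_spec <- function(fs_hz = 1024,
                           epoch_window_ms = c(-100, 400),
                           channels = c("Fz", "FCz", "Cz", "M1p", "M2p"),
                           mastoid_channels = intersect(c("M1p", "M2p"), channels)) {
  stopifnot(
    fs_hz > 60,
    length(epoch_window_ms) == 2,
    epoch_window_ms[1] < 0, epoch_window_ms[2] > 0,
    length(channels) >= 1, !anyDuplicated(channels)
  )
  if (!all(mastoid_channels %in% channels)) {
    stop("mastoid_channels must be a subset of channels", call. = FALSE)
  }
  structure(
    list(fs_hz = fs_hz, epoch_window_ms = as.numeric(epoch_window_ms),
         channels = channels, mastoid_channels = mastoid_channels),
    class = "recording_spec"
  )
}

#' Time grid of an epoch window
#' @param rec A [recording_spec()] (or an `epoch_set`).
#' @return Numeric vector of sample times in ms relative to tone onset.
#' @export
epoch_times <- function(rec) {
  w <- rec$window_ms %||% rec$epoch_window_ms
  n <- round((w[2] - w[1]) * rec$fs_hz / 1000) + 1
  w[1] + (seq_len(n) - 1) * 1000 / rec$fs_hz
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify an ERP component of the synthetic waveform
#'
#' Two temporal shapes are available. `"gaussian"` is a Gaussian pulse
#' with peak at `center_ms` and temporal SD `width_ms` (used for N1 and
#' MMN). `"plateau"` is zero before `center_ms`, rises with a raised
#' cosine over `width_ms`, and stays at 1 for the rest of the epoch
#' (used for the slow repetition positivity, so that the pre-stimulus
#' baseline stays clean).
#'
#' Per-trial amplitude starts at `amp_uv` and may be modulated by the
#' trial's stimulation history:
#' * `modulation = "adaptation_gain"`: amplitude is
#'   `amp_uv * (1 - strength * S)` with `S` the tonotopic adaptation
#'   score (see [adaptation_scores()]); the parameters come from the
#'   `adapt` argument of the simulators, and `amp_uv` defaults to its
#'   `base_n1_uv`. This is the N1 mechanism.
#' * `modulation = "repetition_slope"`: amplitude is
#'   `amp_uv + slope_uv * S_rep` with `S_rep` computed from `mod_params`
#'   (a narrow-kernel, slow-decay [adaptation_params()]), so that exact
#'   frequency repeats grow the component. This is the
#'   repetition-positivity mechanism that makes heavily repeated
#'   standards more positive than rare control tones.
#'
#' `roles`/`conditions` restrict the component to matching tone events
#' (e.g. the MMN is applied only to oddball deviants).
#'
#' @param name Component label.
#' @param shape `"gaussian"` or `"plateau"`.
#' @param center_ms Peak latency (gaussian) or ramp onset (plateau), ms.
#' @param width_ms Temporal SD (gaussian) or ramp duration (plateau), ms.
#' @param amp_uv Frontocentral amplitude in microvolts (`NA` for the N1:
#'   taken from the adaptation parameters at simulation time).
#' @param mastoid_gain Signed scale applied at mastoid-proxy channels.
#' @param roles,conditions Optional character filters on event metadata.
#' @param modulation `"none"`, `"adaptation_gain"`, or
#'   `"repetition_slope"`.
#' @param slope_uv Slope for `"repetition_slope"` modulation, microvolts
#'   per unit repetition score.
#' @param mod_params [adaptation_params()] for `"repetition_slope"`.
#' @return A list of class `"component_spec"`.
#' @export
component_spec <- function(name, shape = c("gaussian", "plateau"),
                           center_ms, width_ms, amp_uv,
                           mastoid_gain = -0.5,
                           roles = NULL, conditions = NULL,
                           modulation = c("none", "adaptation_gain",
                                          "repetition_slope"),
                           slope_uv = 0, mod_params = NULL) {
  shape <- match.arg(shape)
  modulation <- match.arg(modulation)
  stopifnot(width_ms > 0)
  if (modulation == "repetition_slope" && is.null(mod_params)) {
    stop("repetition_slope modulation needs mod_params", call. = FALSE)
  }
  structure(
    list(name = name, shape = shape, center_ms = center_ms,
         width_ms = width_ms, amp_uv = amp_uv, mastoid_gain = mastoid_gain,
         roles = roles, conditions = conditions, modulation = modulation,
         slope_uv = slope_uv, mod_params = mod_params),
    class = "component_spec"
  )
}

#' Calibrated default component set
#'
#' Three components whose defaults are calibrated so that a noise-free
#' simulation of the full design reproduces the reference frontocentral
#' window means (N1 window: 0.66, -0.55, -0.58, -0.72 microvolts for
#' standard, deviant, cascade, and no-repetition tones; MMN window:
#' 1.91, -0.76, 0.74, 0.76). The calibration solve ships in
#' `scripts/calibrate.R`.
#'
#' @param mmn_uv MMN amplitude (negative, microvolts), applied to oddball
#'   deviants only.
#' @param rep_pos_base_uv,rep_pos_slope_uv Baseline and
#'   repetition-score slope of the slow positivity.
#' @return A list of [component_spec()] objects.
#' @export
default_components <- function(mmn_uv = -2.237,
                               rep_pos_base_uv = 0.763,
                               rep_pos_slope_uv = 1.421) {
  list(
    component_spec("N1", "gaussian", center_ms = 93, width_ms = 16,
                   amp_uv = NA_real_, mastoid_gain = -0.5,
                   modulation = "adaptation_gain"),
    component_spec("MMN", "gaussian", center_ms = 140, width_ms = 15,
                   amp_uv = mmn_uv, mastoid_gain = -0.5,
                   roles = "deviant", conditions = "oddball"),
    component_spec("rep_pos", "plateau", center_ms = 30, width_ms = 50,
                   amp_uv = rep_pos_base_uv, mastoid_gain = -0.3,
                   modulation = "repetition_slope",
                   slope_uv = rep_pos_slope_uv,
                   mod_params = adaptation_params(
                     base_n1_uv = 0, strength = 0,
                     tonotopic_sd_oct = 0.02,
                     recency_tau_trials = 8, history_len = 16
                   ))
  )
}

#' Additive noise model
#'
#' @param sd_uv Marginal per-sample noise SD in microvolts.
#' @param model `"ar1"` (default, lag-1 autoregressive across samples,
#'   independent across trials and channels) or `"white"`.
#' @param ar1_rho Lag-1 autocorrelation for the AR(1) model.
#' @return A list of class `"noise_spec"`.
#' @export
noise_spec <- function(sd_uv = 13, model = c("ar1", "white"),
                       ar1_rho = 0.95) {
  model <- match.arg(model)
  stopifnot(sd_uv >= 0, abs(ar1_rho) < 1)
  structure(list(sd_uv = sd_uv, model = model, ar1_rho = ar1_rho),
            class = "noise_spec")
}

component_profile <- function(comp, t_ms) {
  switch(comp$shape,
    gaussian = exp(-(t_ms - comp$center_ms)^2 / (2 * comp$width_ms^2)),
    plateau = {
      x <- (t_ms - comp$center_ms) / comp$width_ms
      ifelse(x <= 0, 0, ifelse(x >= 1, 1, (1 - cos(pi * x)) / 2))
    }
  )
}

component_amplitudes <- function(comp, seq, adapt, amp_scale) {
  amp <- comp$amp_uv
  if (comp$modulation == "adaptation_gain") {
    if (is.na(amp)) amp <- adapt$base_n1_uv
    s <- adaptation_scores(seq, adapt)
    a <- amp * (1 - adapt$strength * s)
  } else if (comp$modulation == "repetition_slope") {
    s <- adaptation_scores(seq, comp$mod_params)
    a <- amp + comp$slope_uv * s
  } else {
    a <- rep(amp, nrow(seq))
  }
  if (!is.null(comp$roles)) a[!(seq$role %in% comp$roles)] <- 0
  if (!is.null(comp$conditions)) a[!(seq$condition %in% comp$conditions)] <- 0
  a * amp_scale
}

simulate_noise <- function(n_trial, n_chan, n_samp, noise) {
  if (noise$sd_uv == 0) {
    return(array(0, dim = c(n_trial, n_chan, n_samp)))
  }
  k <- n_trial * n_chan
  if (noise$model == "white") {
    e <- matrix(stats::rnorm(n_samp * k, sd = noise$sd_uv), nrow = n_samp)
  } else {
    rho <- noise$ar1_rho
    e <- matrix(stats::rnorm(n_samp * k, sd = noise$sd_uv * sqrt(1 - rho^2)),
                nrow = n_samp)
    # stationary start: first innovation at the marginal SD
    e[1, ] <- stats::rnorm(k, sd = noise$sd_uv)
    e <- stats::filter(e, rho, method = "recursive")
  }
  aperm(array(as.numeric(e), dim = c(n_samp, n_trial, n_chan)), c(2, 3, 1))
}

#' Simulate one block of epoched EEG
#'
#' Builds each trial's waveform as the sum of the component set
#' (adaptation-scaled N1, deviant-only MMN, repetition positivity),
#' scales components at mastoid-proxy channels by their signed mastoid
#' gain, and adds noise. Warm-up trials are simulated (they shape the
#' adaptation history of the first analyzed trials) and stay flagged in
#' the event table.
#'
#' @param seq A `tone_sequence` (one block).
#' @param rec A [recording_spec()].
#' @param components List of [component_spec()]s.
#' @param adapt [adaptation_params()] driving the N1.
#' @param noise A [noise_spec()].
#' @param subject_id,ring_condition Metadata carried into the epoch set.
#' @param amp_scale Multiplicative between-subject amplitude factor.
#' @return An object of class `"epoch_set"`: a list with `data`
#'   (trials x channels x samples array, microvolts), `events`, and the
#'   recording metadata.
#' @export
simulate_epochs <- function(seq, rec = recording_spec(),
                            components = default_components(),
                            adapt = adaptation_params(),
                            noise = noise_spec(),
                            subject_id = "s01",
                            ring_condition = "one_letter",
                            amp_scale = 1) {
  t_ms <- epoch_times(rec)
  n_samp <- length(t_ms)
  n_trial <- nrow(seq)
  n_chan <- length(rec$channels)
  is_mastoid <- rec$channels %in% rec$mastoid_channels

  prof <- vapply(components, component_profile, numeric(n_samp), t_ms = t_ms)
  amps <- vapply(components, component_amplitudes, numeric(n_trial),
                 seq = seq, adapt = adapt, amp_scale = amp_scale)
  mast <- vapply(components, function(c) c$mastoid_gain, numeric(1))

  data <- simulate_noise(n_trial, n_chan, n_samp, noise)
  for (ch in seq_len(n_chan)) {
    g <- ifelse(is_mastoid[ch], mast, 1)
    data[, ch, ] <- data[, ch, ] + amps %*% t(prof * rep(g, each = n_samp))
  }
  dimnames(data) <- list(NULL, rec$channels, NULL)

  structure(
    list(data = data, events = seq, subject_id = subject_id,
         ring_condition = ring_condition, fs_hz = rec$fs_hz,
         window_ms = rec$epoch_window_ms, channels = rec$channels,
         mastoid_channels = rec$mastoid_channels),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> subject %s, %s: %d trials x %d channels x %d samples (%g Hz)\n",
    x$subject_id, x$events$condition[1], dim(x$data)[1], dim(x$data)[2],
    dim(x$data)[3], x$fs_hz
  ))
  invisible(x)
}

#' Simulate all blocks of one subject
#'
#' @param sequences Named list of `tone_sequence` blocks (e.g. oddball,
#'   cascade, norep), as produced by the sequence generators.
#' @inheritParams simulate_epochs
#' @param seed Optional integer; when given, the RNG state is set before
#'   simulation so the subject is reproducible in isolation.
#' @return Named list of `epoch_set`s, one per sequence.
#' @export
simulate_subject <- function(sequences, rec = recording_spec(),
                             components = default_components(),
                             adapt = adaptation_params(),
                             noise = noise_spec(),
                             subject_id = "s01",
                             ring_condition = "one_letter",
                             amp_scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(sequences, simulate_epochs, rec = rec, components = components,
         adapt = adapt, noise = noise, subject_id = subject_id,
         ring_condition = ring_condition, amp_scale = amp_scale)
}

#' Simulate a multi-subject study
#'
#' Each subject gets freshly generated sequences (one block per
#' condition), an amplitude scale factor drawn from
#' `Normal(1, between_subject_sd)` (truncated at 0) applied to all
#' component amplitudes, and a behavioral plus-count maximum error drawn
#' from `Normal(behavior_mean, behavior_sd)` (truncated at 0) for the
#' exclusion rules. Reproducible from `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [seq_spec()] shared by all blocks.
#' @inheritParams simulate_epochs
#' @param between_subject_sd SD of the per-subject amplitude scale.
#' @param behavior_mean,behavior_sd Distribution of the per-subject
#'   maximum plus-count error.
#' @param conditions Which blocks to generate per subject.
#' @param seed Integer seed.
#' @return A list of class `"epoch_study"`: `subjects` is a list with
#'   elements `epochs` (named list of `epoch_set`s), `amp_scale`,
#'   `max_count_error`, `subject_id`.
#' @export
simulate_study <- function(n_subjects = 26, spec = seq_spec(),
                           rec = recording_spec(),
                           components = default_components(),
                           adapt = adaptation_params(),
                           noise = noise_spec(),
                           between_subject_sd = 0.15,
                           behavior_mean = 5.05, behavior_sd = 1.04,
                           conditions = c("oddball", "cascade", "norep"),
                           seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.null(seed)) set.seed(seed)
  subjects <- lapply(seq_len(n_subjects), function(i) {
    sid <- sprintf("s%02d", i)
    sim_one_subject(sid, spec, rec, components, adapt, noise,
                    between_subject_sd, behavior_mean, behavior_sd,
                    conditions)
  })
  structure(
    list(subjects = subjects,
         params = list(spec = spec, rec = rec, components = components,
                       adapt = adapt, noise = noise,
                       between_subject_sd = between_subject_sd)),
    class = "epoch_study"
  )
}

make_sequences <- function(spec, conditions) {
  gens <- list(oddball = make_oddball_sequence,
               cascade = make_cascade_sequence,
               norep = make_norep_sequence)
  stopifnot(all(conditions %in% names(gens)))
  stats::setNames(lapply(conditions, function(cn) gens[[cn]](spec)), conditions)
}

sim_one_subject <- function(sid, spec, rec, components, adapt, noise,
                            between_subject_sd, behavior_mean, behavior_sd,
                            conditions, sequences = NULL) {
  amp_scale <- max(stats::rnorm(1, 1, between_subject_sd), 0)
  max_count_error <- max(stats::rnorm(1, behavior_mean, behavior_sd), 0)
  seqs <- sequences %||% make_sequences(spec, conditions)
  epochs <- simulate_subject(seqs, rec, components, adapt, noise,
                             subject_id = sid, amp_scale = amp_scale)
  list(epochs = epochs, amp_scale = amp_scale,
       max_count_error = max_count_error, subject_id = sid)
}
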