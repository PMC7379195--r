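#' Baseline-correct an epoch set
#'
#' Subtracts, per trial and channel, the mean of the pre-stimulus
#' interval (epoch start up to, excluding, 0 ms). Idempotent.
#'
#' @param epochs An `epoch_set`.
#' @return The corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs) {
  t_ms <- epoch_times(epochs)
  base <- t_ms < 0
  if (!any(base)) stop("epoch window has no pre-stimulus interval", call. = FALSE)
  d <- dim(epochs$data)
  bl <- rowMeans(matrix(epochs$data[, , base, drop = FALSE], d[1] * d[2]))
  epochs$data <- epochs$data - bl # recycles over samples
  epochs
}

#' Per-trial amplitude ranges
#'
#' The amplitude range of a trial is the per-channel max minus min over
#' all samples, maximized over the stated channels -- the quantity the
#' artifact-rejection policy operates on. Because the range is computed
#' within channel, it is invariant to baseline correction.
#'
#' @param epochs An `epoch_set`.
#' @param channels Channel subset; defaults to the non-mastoid
#'   (frontocentral) channels.
#' @return A tibble with `trial`, `range_uv`, and the trial's role.
#' @export
amplitude_ranges <- function(epochs, channels = NULL) {
  channels <- channels %||% setdiff(epochs$channels, epochs$mastoid_channels)
  ci <- match(channels, epochs$channels)
  if (anyNA(ci)) stop("unknown channel(s): ",
                      paste(channels[is.na(ci)], collapse = ", "), call. = FALSE)
  x <- epochs$data[, ci, , drop = FALSE]
  hi <- x[, , 1]
  lo <- x[, , 1]
  for (s in seq_len(dim(x)[3])[-1]) {
    hi <- pmax(hi, x[, , s])
    lo <- pmin(lo, x[, , s])
  }
  per_chan <- matrix(hi - lo, nrow = dim(x)[1])
  rng <- apply(per_chan, 1, max)
  tibble::tibble(trial = seq_along(rng), range_uv = rng,
                 role = epochs$events$role)
}

#' Artifact-rejection policy
#'
#' `mode = "fixed_uv"` rejects trials whose amplitude range exceeds
#' `threshold_uv`. `mode = "percentile"` (the default policy) uses the
#' subject's own range distribution: the cutoff is the `percentile`
#' quantile of the per-trial ranges, capped at `threshold_uv` --
#' whichever is lower. Rejection is blind to condition labels.
#'
#' @param mode `"percentile"` or `"fixed_uv"`.
#' @param threshold_uv Fixed cutoff (and cap for the percentile mode).
#' @param percentile Upper quantile of per-trial ranges, in (0, 1].
#' @return A list of class `"rejection_policy"`.
#' @export
rejection_policy <- function(mode = c("percentile", "fixed_uv"),
                             threshold_uv = 200, percentile = 0.99) {
  mode <- match.arg(mode)
  stopifnot(threshold_uv > 0, percentile > 0, percentile <= 1)
  structure(list(mode = mode, threshold_uv = threshold_uv,
                 percentile = percentile),
            class = "rejection_policy")
}

#' Reject artifact trials
#'
#' @param epochs An `epoch_set`.
#' @param policy A [rejection_policy()].
#' @param channels Channels over which ranges are computed (see
#'   [amplitude_ranges()]).
#' @return A list: `epochs` (kept trials), `log` (one-row tibble with
#'   the cutoff, kept/total counts and retention), `kept` (logical
#'   per-trial vector).
#' @export
reject_artifacts <- function(epochs, policy = rejection_policy(),
                             channels = NULL) {
  rng <- amplitude_ranges(epochs, channels)$range_uv
  cutoff <- switch(policy$mode,
    fixed_uv = policy$threshold_uv,
    percentile = min(stats::quantile(rng, policy$percentile, names = FALSE),
                     policy$threshold_uv)
  )
  kept <- rng <= cutoff
  if (!any(kept)) stop("rejection cutoff removes all trials", call. = FALSE)
  out <- epochs
  out$data <- epochs$data[kept, , , drop = FALSE]
  out$events <- epochs$events[kept, ]
  log <- tibble::tibble(
    subject_id = epochs$subject_id,
    condition = epochs$events$condition[1],
    cutoff_uv = cutoff,
    n_total = length(kept), n_kept = sum(kept),
    retention = mean(kept)
  )
  list(epochs = out, log = log, kept = kept)
}

new_erp_average <- function(data, n_trials, selector, fs_hz, window_ms,
                            channels) {
  structure(
    list(data = data, n_trials = n_trials, selector = selector,
         fs_hz = fs_hz, window_ms = window_ms, channels = channels),
    class = "erp_average"
  )
}

#' Average epochs into an ERP
#'
#' Pointwise arithmetic mean over the trials matched by the selector
#' expressions, evaluated against the event table (e.g.
#' `role == "deviant"`). Warm-up trials are always excluded.
#'
#' @param epochs An `epoch_set`.
#' @param ... Filter expressions on the event columns.
#' @return An `erp_average`: channels x samples matrix plus metadata.
#' @export
average_erp <- function(epochs, ...) {
  dots <- rlang::enquos(...)
  ev <- dplyr::mutate(epochs$events, .row = dplyr::row_number())
  sel <- dplyr::filter(ev, !.data$is_warmup, !!!dots)
  if (nrow(sel) == 0) stop("selector matches no analyzed trials", call. = FALSE)
  sub <- epochs$data[sel$.row, , , drop = FALSE]
  m <- colMeans(sub) # averages over the trial dimension
  lab <- paste(vapply(dots, rlang::as_label, character(1)),
               collapse = " & ")
  new_erp_average(m, nrow(sel), if (nzchar(lab)) lab else "all",
                  epochs$fs_hz, epochs$window_ms, epochs$channels)
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average> %s: %d trials, %d channels, %d samples\n",
              x$selector, x$n_trials, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Combine subject ERPs into a grand average
#'
#' Trial-count-weighted by default, so the grand average equals the
#' average over all contributing trials.
#'
#' @param erps List of `erp_average`s on identical grids.
#' @param weight_by_trials Weight subjects by their trial counts;
#'   `FALSE` gives the unweighted mean of subject ERPs.
#' @return An `erp_average`.
#' @export
grand_average <- function(erps, weight_by_trials = TRUE) {
  stopifnot(length(erps) >= 1)
  w <- if (weight_by_trials) {
    vapply(erps, function(e) e$n_trials, numeric(1))
  } else {
    rep(1, length(erps))
  }
  acc <- Reduce(`+`, Map(function(e, wi) e$data * wi, erps, w))
  e1 <- erps[[1]]
  new_erp_average(acc / sum(w), sum(vapply(erps, function(e) e$n_trials,
                                           numeric(1))),
                  paste0("grand(", e1$selector, ")"),
                  e1$fs_hz, e1$window_ms, e1$channels)
}

#' Zero-phase low-pass filter an ERP
#'
#' 4th-order Butterworth applied forward-backward
#' ([signal::filtfilt()]), so DC is preserved and peak latencies do not
#' shift. Used for peak identification and display; window means are
#' extracted from unfiltered averages.
#'
#' @param erp An `erp_average`.
#' @param cutoff_hz Cutoff frequency.
#' @return The filtered `erp_average`.
#' @export
lowpass_erp <- function(erp, cutoff_hz = 30) {
  if (erp$fs_hz <= 2 * cutoff_hz) {
    stop("sampling rate must exceed twice the cutoff", call. = FALSE)
  }
  bf <- signal::butter(4, cutoff_hz / (erp$fs_hz / 2), type = "low")
  erp$data <- t(apply(erp$data, 1, function(ch) signal::filtfilt(bf, ch)))
  erp
}

#' Find a component peak latency
#'
#' Latency of the extremum of the channel-averaged waveform within the
#' search window; ties break to the earliest sample. The waveform is
#' low-pass filtered first (30 Hz by default), following the convention
#' that peaks are defined on the smoothed mean wave.
#'
#' @param erp An `erp_average`.
#' @param polarity `"negative"` (peak negativity) or `"positive"`.
#' @param search_window_ms `c(start, end)` in ms, inside the epoch.
#' @param channels Channels averaged before peak picking; default
#'   frontocentral (non-mastoid) channels.
#' @param lowpass_hz Low-pass cutoff applied before peak picking
#'   (`NULL` to skip).
#' @return A list: `latency_ms`, `value_uv`, and `at_edge` (`TRUE` when
#'   the extremum sits on a window edge, i.e. the peak is not
#'   bracketed).
#' @export
find_peak <- function(erp, polarity = c("negative", "positive"),
                      search_window_ms, channels = NULL, lowpass_hz = 30) {
  polarity <- match.arg(polarity)
  if (!is.null(lowpass_hz)) erp <- lowpass_erp(erp, lowpass_hz)
  channels <- channels %||% setdiff(erp$channels,
                                    attr(erp, "mastoid_channels") %||%
                                      grep("^M", erp$channels, value = TRUE))
  ci <- match(channels, erp$channels)
  if (anyNA(ci)) stop("unknown channel(s) in find_peak", call. = FALSE)
  t_ms <- epoch_times(erp)
  inw <- which(t_ms >= search_window_ms[1] & t_ms <= search_window_ms[2])
  if (length(inw) < 3) stop("search window too narrow for the grid", call. = FALSE)
  wave <- colMeans(erp$data[ci, inw, drop = FALSE])
  i <- if (polarity == "negative") which.min(wave) else which.max(wave)
  list(latency_ms = t_ms[inw[i]], value_uv = wave[i],
       at_edge = i == 1 || i == length(inw))
}

#' Amplitude-extraction window
#'
#' A data-driven interval `[center - half_width, center + half_width]`
#' with the channel set over which the mean is taken.
#'
#' @param name Window label (`"N1"` or `"MMN"`).
#' @param center_ms Detected peak latency.
#' @param half_width_ms Half-width in ms (15 for N1, 25 for MMN).
#' @param channels Channels entering the mean.
#' @return A list of class `"component_window"`.
#' @export
component_window <- function(name, center_ms, half_width_ms,
                             channels = c("Fz", "FCz", "Cz")) {
  stopifnot(half_width_ms > 0)
  structure(list(name = name, center_ms = center_ms,
                 half_width_ms = half_width_ms, channels = channels),
            class = "component_window")
}

#' Derive N1 and MMN windows from oddball data
#'
#' The N1 window centres on the peak negativity of the oddball-standard
#' ERP near 100 ms; the MMN window centres on the peak negativity of the
#' deviant-minus-standard difference wave between 100 and 250 ms. Both
#' derive from oddball trials only, so they are independent of the
#' cascade and no-repetition data they are later applied to.
#'
#' @param standard_erp Oddball-standard `erp_average` (grand average).
#' @param difference_erp Deviant-minus-standard `erp_average`.
#' @param channels Frontocentral channels defining the peaks and means.
#' @param n1_search_ms,mmn_search_ms Peak search windows.
#' @param n1_half_width_ms,mmn_half_width_ms Window half-widths.
#' @return A list with `component_window`s `n1` and `mmn`.
#' @export
derive_windows <- function(standard_erp, difference_erp,
                           channels = c("Fz", "FCz", "Cz"),
                           n1_search_ms = c(60, 160),
                           mmn_search_ms = c(100, 250),
                           n1_half_width_ms = 15, mmn_half_width_ms = 25) {
  n1 <- find_peak(standard_erp, "negative", n1_search_ms, channels)
  mmn <- find_peak(difference_erp, "negative", mmn_search_ms, channels)
  list(
    n1 = component_window("N1", n1$latency_ms, n1_half_width_ms, channels),
    mmn = component_window("MMN", mmn$latency_ms, mmn_half_width_ms, channels)
  )
}

#' Mean amplitude within a component window
#'
#' Mean over the window's channels and all samples with
#' `center - half_width <= t <= center + half_width` (inclusive bounds
#' on the sample grid).
#'
#' @param erp An `erp_average`.
#' @param window A [component_window()].
#' @return Scalar mean amplitude in microvolts.
#' @export
window_mean <- function(erp, window) {
  t_ms <- epoch_times(erp)
  lo <- window$center_ms - window$half_width_ms
  hi <- window$center_ms + window$half_width_ms
  if (lo < t_ms[1] || hi > t_ms[length(t_ms)]) {
    stop("window extends beyond the epoch", call. = FALSE)
  }
  ci <- match(window$channels, erp$channels)
  if (anyNA(ci)) stop("window channels missing from ERP", call. = FALSE)
  mean(erp$data[ci, t_ms >= lo & t_ms <= hi, drop = FALSE])
}

#' Difference wave of two ERPs
#'
#' Pointwise `a - b` on identical grids (e.g. deviant minus standard).
#'
#' @param a,b `erp_average`s with identical channels, sampling rate and
#'   window.
#' @return An `erp_average` (with `n_trials` set to `NA`).
#' @export
difference_wave <- function(a, b) {
  if (!identical(a$channels, b$channels) || a$fs_hz != b$fs_hz ||
      !identical(a$window_ms, b$window_ms)) {
    stop("ERPs are on different grids", call. = FALSE)
  }
  new_erp_average(a$data - b$data, NA_integer_,
                  paste0("(", a$selector, ") - (", b$selector, ")"),
                  a$fs_hz, a$window_ms, a$channels)
}

#' Apply subject exclusion rules
#'
#' Three preregistration-style rules:
#' * `behavior_outlier`: the subject's maximum plus-count error exceeds
#'   (strictly) the across-subject mean plus `behavior_sd_mult` SDs;
#' * `low_retention`: post-rejection retention below
#'   `min_retention` for any primary-analysis ERP;
#' * `no_n1`: automated proxy for the visual N1-absence vote -- the
#'   subject's standard-trial N1 trough (N1-window mean minus the mean
#'   of a post-N1 flank window) is not more negative than
#'   `-n1_z * noise_sd`, where `noise_sd` is the SD of the subject's
#'   pre-stimulus ERP samples.
#'
#' @param subjects A tibble with one row per subject and columns
#'   `subject_id`, `max_count_error`, `min_retention` (the subject's
#'   worst retention across primary ERPs), `n1_depth_uv`, and
#'   `baseline_noise_sd`.
#' @param behavior_sd_mult SD multiplier of the behavioral rule.
#' @param min_retention Retention threshold.
#' @param n1_z z-threshold of the N1-absence proxy.
#' @return The input tibble with logical flag columns and `excluded`.
#' @export
apply_exclusions <- function(subjects, behavior_sd_mult = 2,
                             min_retention = 0.70, n1_z = 2) {
  m <- mean(subjects$max_count_error)
  s <- stats::sd(subjects$max_count_error)
  if (is.na(s)) s <- 0
  retention_thr <- min_retention # avoid masking by the data column
  dplyr::mutate(
    subjects,
    behavior_outlier = .data$max_count_error > m + behavior_sd_mult * s,
    low_retention = .data$min_retention < retention_thr,
    no_n1 = .data$n1_depth_uv > -n1_z * .data$baseline_noise_sd,
    excluded = .data$behavior_outlier | .data$low_retention | .data$no_n1
  )
}

#' N1 presence diagnostics of a standard-trial ERP
#'
#' Returns the trough depth (N1-window mean minus the mean of a flank
#' window after the N1) and the SD of the pre-stimulus samples, the two
#' quantities the automated N1-absence proxy uses.
#'
#' @param erp The subject's oddball-standard `erp_average`.
#' @param n1_window The N1 [component_window()].
#' @param flank_offset_ms Offset of the flank window (same width as the
#'   N1 window) after the N1 center.
#' @return A list: `n1_depth_uv`, `baseline_noise_sd`.
#' @export
n1_diagnostics <- function(erp, n1_window, flank_offset_ms = 50) {
  flank <- component_window("flank", n1_window$center_ms + flank_offset_ms,
                            n1_window$half_width_ms, n1_window$channels)
  t_ms <- epoch_times(erp)
  ci <- match(n1_window$channels, erp$channels)
  base <- erp$data[ci, t_ms < 0, drop = FALSE]
  list(
    n1_depth_uv = window_mean(erp, n1_window) - window_mean(erp, flank),
    baseline_noise_sd = stats::sd(as.numeric(base))
  )
}
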