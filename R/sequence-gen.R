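#' Specify a tone-sequence block
#'
#' Bundles the parameters shared by the three block generators
#' ([make_oddball_sequence()], [make_cascade_sequence()],
#' [make_norep_sequence()]): the five-tone frequency ladder, the block
#' length, the stimulus onset asynchrony, and the inter-deviant gap
#' distribution used by the oddball rule.
#'
#' The deviant (oddball condition) and the control tone (cascade and
#' no-repetition conditions) are the same ladder entry, `deviant_index`.
#' In the oddball condition every other analyzed trial carries the
#' standard, defined as the next ladder entry (`deviant_index + 1`).
#'
#' @param frequency_ladder Strictly increasing tone frequencies in Hz.
#' @param n_trials Number of analyzed trials per block (warm-up trials are
#'   added on top). Must be divisible by 8.
#' @param soa_ms Stimulus onset asynchrony in ms (onset-to-onset).
#' @param tone_dur_ms Tone duration in ms (metadata only; event times are
#'   nominal onsets).
#' @param deviant_index 1-based position in the ladder of the
#'   deviant/control tone.
#' @param gap_mean,gap_sd,gap_min,gap_max Parameters of the discretized
#'   truncated normal distribution of inter-deviant gaps (number of
#'   standards between successive deviants), oddball condition only.
#' @return A list of class `"seq_spec"`.
#' @export
seq_spec <- function(frequency_ladder = c(500, 550, 605, 666, 732),
                     n_trials = 360, soa_ms = 500, tone_dur_ms = 100,
                     deviant_index = 1,
                     gap_mean = 7, gap_sd = 2, gap_min = 3, gap_max = 11) {
  stopifnot(
    length(frequency_ladder) >= 2,
    all(diff(frequency_ladder) > 0),
    n_trials >= 8, n_trials %% 8 == 0,
    soa_ms > 0, tone_dur_ms > 0,
    deviant_index >= 1, deviant_index < length(frequency_ladder)
  )
  if (gap_sd <= 0) stop("gap_sd must be > 0", call. = FALSE)
  if (gap_min > gap_max) stop("gap_min must be <= gap_max", call. = FALSE)
  if (gap_min < 3) stop("gap_min must be >= 3", call. = FALSE)
  if (gap_mean < gap_min || gap_mean > gap_max) {
    stop("gap_mean must lie within [gap_min, gap_max]", call. = FALSE)
  }
  structure(
    list(
      frequency_ladder = as.numeric(frequency_ladder),
      n_trials = as.integer(n_trials),
      soa_ms = soa_ms,
      tone_dur_ms = tone_dur_ms,
      deviant_index = as.integer(deviant_index),
      gap_mean = gap_mean, gap_sd = gap_sd,
      gap_min = as.integer(gap_min), gap_max = as.integer(gap_max)
    ),
    class = "seq_spec"
  )
}

#' Sample inter-deviant gaps
#'
#' Draws integer gaps (number of standards between successive deviants)
#' from a normal distribution discretized onto the integers of
#' `[gap_min, gap_max]`: each integer receives mass proportional to the
#' normal density at that integer, renormalized over the support. With a
#' mean centred in the support the distribution is symmetric.
#'
#' @param n_gaps Number of gaps to draw.
#' @inheritParams seq_spec
#' @return Integer vector of length `n_gaps`, all within
#'   `[gap_min, gap_max]`.
#' @export
sample_interdeviant_gaps <- function(n_gaps, gap_mean = 7, gap_sd = 2,
                                     gap_min = 3, gap_max = 11) {
  stopifnot(n_gaps >= 1)
  if (gap_sd <= 0) stop("gap_sd must be > 0", call. = FALSE)
  if (gap_min > gap_max) stop("gap_min must be <= gap_max", call. = FALSE)
  support <- seq.int(gap_min, gap_max)
  prob <- stats::dnorm(support, mean = gap_mean, sd = gap_sd)
  support[sample.int(length(support), n_gaps, replace = TRUE,
                     prob = prob / sum(prob))]
}

new_tone_sequence <- function(trial_index, frequency_hz, role, condition,
                              set_index, is_warmup, spec) {
  out <- tibble::tibble(
    trial_index = as.integer(trial_index),
    onset_ms = as.numeric(trial_index) * spec$soa_ms,
    frequency_hz = as.numeric(frequency_hz),
    role = role,
    condition = condition,
    set_index = as.integer(set_index),
    is_warmup = is_warmup
  )
  attr(out, "seq_spec") <- spec
  class(out) <- c("tone_sequence", class(out))
  out
}

#' Generate an oddball block
#'
#' The deviant occupies exactly 1/8 of the analyzed trials; all other
#' analyzed trials carry the standard (the ladder entry above the
#' deviant). Deviant placement follows the inter-deviant gap distribution
#' of the spec, laid left to right, with the whole gap vector redrawn
#' (bounded retries) if the final deviant does not fit into the block.
#' Seven warm-up standards precede the block and count toward the first
#' inter-deviant gap.
#'
#' @param spec A [seq_spec()].
#' @param n_warmup Number of warm-up standards preceding the block.
#' @param max_retries Bound on gap-vector redraws before erroring.
#' @return A `tone_sequence` tibble with one row per tone event.
#' @export
make_oddball_sequence <- function(spec = seq_spec(), n_warmup = 7,
                                  max_retries = 1000) {
  stopifnot(inherits(spec, "seq_spec"))
  n <- spec$n_trials
  n_dev <- n %/% 8L
  dev_freq <- spec$frequency_ladder[spec$deviant_index]
  std_freq <- spec$frequency_ladder[spec$deviant_index + 1L]

  positions <- NULL
  for (try in seq_len(max_retries)) {
    gaps <- sample_interdeviant_gaps(n_dev, spec$gap_mean, spec$gap_sd,
                                     spec$gap_min, spec$gap_max)
    # warm-up standards count toward the first gap
    pos <- cumsum(c(max(gaps[1] - n_warmup, 0L), gaps[-1] + 1L))
    if (pos[n_dev] <= n - 1L) {
      positions <- pos
      break
    }
  }
  if (is.null(positions)) {
    stop("could not place ", n_dev, " deviants within ", n,
         " trials after ", max_retries, " retries", call. = FALSE)
  }

  freq <- rep(std_freq, n)
  role <- rep("standard", n)
  freq[positions + 1L] <- dev_freq
  role[positions + 1L] <- "deviant"

  new_tone_sequence(
    trial_index = seq_len(n_warmup + n) - 1L,
    frequency_hz = c(rep(std_freq, n_warmup), freq),
    role = c(rep("warmup", n_warmup), role),
    condition = "oddball",
    set_index = -1L,
    is_warmup = rep(c(TRUE, FALSE), c(n_warmup, n)),
    spec = spec
  )
}

# The 8-tone cascade cycle as ladder positions: up the ladder and back down.
cascade_cycle <- function(spec) {
  k <- length(spec$frequency_ladder)
  idx <- c(seq_len(k), rev(seq_len(k))[-c(1, k)])
  spec$frequency_ladder[idx]
}

cascade_roles <- function(freq, spec) {
  ifelse(freq == spec$frequency_ladder[spec$deviant_index], "control", "other")
}

#' Generate a cascade block
#'
#' The analyzed trials repeat the fixed up-and-down frequency cycle
#' (ladder positions 1,2,3,4,5,4,3,2); the control tone (ladder position
#' `deviant_index`) therefore occupies exactly 1/8 of analyzed trials and
#' no two consecutive tones share a frequency. The warm-up is one cycle
#' with the control tone omitted.
#'
#' @inheritParams make_oddball_sequence
#' @return A `tone_sequence` tibble.
#' @export
make_cascade_sequence <- function(spec = seq_spec()) {
  stopifnot(inherits(spec, "seq_spec"))
  cyc <- cascade_cycle(spec)
  n_sets <- spec$n_trials %/% 8L
  warm <- cyc[cyc != spec$frequency_ladder[spec$deviant_index]]
  freq <- rep(cyc, n_sets)

  new_tone_sequence(
    trial_index = seq_len(length(warm) + length(freq)) - 1L,
    frequency_hz = c(warm, freq),
    role = c(rep("warmup", length(warm)), cascade_roles(freq, spec)),
    condition = "cascade",
    set_index = c(rep(-1L, length(warm)), rep(seq_len(n_sets) - 1L, each = 8L)),
    is_warmup = rep(c(TRUE, FALSE), c(length(warm), length(freq))),
    spec = spec
  )
}

# Uniformly sample a permutation of `tones` with no adjacent repeats and
# first element != `prev`; unbiased among valid permutations by rejection.
permute_no_repeat <- function(tones, prev = NA_real_, max_tries = 10000) {
  for (i in seq_len(max_tries)) {
    cand <- sample(tones)
    if (!anyNA(prev) && cand[1] == prev) next
    if (!any(cand[-1] == cand[-length(cand)])) return(cand)
  }
  stop("rejection budget exhausted while permuting a no-repetition set",
       call. = FALSE)
}

#' Generate a no-repetition block
#'
#' Each analyzed 8-tone set is an independent uniform permutation of the
#' cascade cycle's frequency multiset, rejection-sampled so that no two
#' consecutive tones share a frequency -- within sets, across set
#' boundaries, and at the junction with the warm-up set. The warm-up is
#' one pseudorandomized 7-tone set without the control tone.
#'
#' @inheritParams make_oddball_sequence
#' @return A `tone_sequence` tibble.
#' @export
make_norep_sequence <- function(spec = seq_spec()) {
  stopifnot(inherits(spec, "seq_spec"))
  cyc <- cascade_cycle(spec)
  n_sets <- spec$n_trials %/% 8L
  warm_tones <- cyc[cyc != spec$frequency_ladder[spec$deviant_index]]

  warm <- permute_no_repeat(warm_tones)
  sets <- vector("list", n_sets)
  prev <- warm[length(warm)]
  for (s in seq_len(n_sets)) {
    sets[[s]] <- permute_no_repeat(cyc, prev)
    prev <- sets[[s]][8]
  }
  freq <- unlist(sets)

  new_tone_sequence(
    trial_index = seq_len(length(warm) + length(freq)) - 1L,
    frequency_hz = c(warm, freq),
    role = c(rep("warmup", length(warm)), cascade_roles(freq, spec)),
    condition = "norep",
    set_index = c(rep(-1L, length(warm)), rep(seq_len(n_sets) - 1L, each = 8L)),
    is_warmup = rep(c(TRUE, FALSE), c(length(warm), length(freq))),
    spec = spec
  )
}

#' Summary statistics of a tone sequence
#'
#' Computes the frequency proportions over analyzed (non-warm-up) trials,
#' the number of adjacent identical-frequency pairs over the entire event
#' list (warm-up junction included), and -- for oddball blocks -- the
#' histogram of inter-deviant gaps.
#'
#' @param seq A `tone_sequence` tibble.
#' @return A list with elements `proportions` (tibble: `frequency_hz`,
#'   `n`, `prop`), `n_adjacent_repeats` (integer), and `gap_histogram`
#'   (tibble `gap`, `n`, or `NULL` for non-oddball sequences).
#' @export
sequence_stats <- function(seq) {
  stopifnot(nrow(seq) >= 1)
  analyzed <- dplyr::filter(seq, !.data$is_warmup)
  proportions <- analyzed |>
    dplyr::count(.data$frequency_hz) |>
    dplyr::mutate(prop = .data$n / sum(.data$n))

  f <- seq$frequency_hz
  n_rep <- if (length(f) > 1) sum(f[-1] == f[-length(f)]) else 0L

  gap_histogram <- NULL
  if (identical(seq$condition[1], "oddball")) {
    dev_pos <- which(analyzed$role == "deviant")
    if (length(dev_pos) >= 2) {
      gaps <- diff(dev_pos) - 1L
      gap_histogram <- tibble::tibble(gap = sort(unique(gaps))) |>
        dplyr::mutate(n = as.integer(table(factor(gaps, levels = .data$gap))))
    }
  }
  list(
    proportions = proportions,
    n_adjacent_repeats = as.integer(n_rep),
    gap_histogram = gap_histogram
  )
}

#' Read/write tone sequences as TSV event tables
#'
#' The on-disk format is a plain tab-separated table with columns
#' `trial_index`, `onset_ms`, `frequency_hz`, `role`, `condition`,
#' `set_index`, `is_warmup`.
#'
#' @param seq A `tone_sequence` tibble.
#' @param path File path.
#' @return `write_sequence_tsv()` returns `seq` invisibly;
#'   `read_sequence_tsv()` returns a tibble.
#' @export
write_sequence_tsv <- function(seq, path) {
  readr::write_tsv(as.data.frame(seq), path)
  invisible(seq)
}

#' @rdname write_sequence_tsv
#' @export
read_sequence_tsv <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      trial_index = readr::col_integer(),
      onset_ms = readr::col_double(),
      frequency_hz = readr::col_double(),
      role = readr::col_character(),
      condition = readr::col_character(),
      set_index = readr::col_integer(),
      is_warmup = readr::col_logical()
    )
  )
}
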