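#' Expected adjacent-repetition percentage under complete randomization
#'
#' For a block containing `m` distinct tones presented `r` times each in
#' a uniformly random order, the probability that an adjacent pair of
#' trials carries the same tone is `m * r * (r - 1) / (N * (N - 1))`
#' with `N = m * r` -- the chance that two positions of a random
#' multiset permutation hold the same type. Returned as a percentage.
#'
#' @param n_tone_types Number of distinct tones `m`.
#' @param reps_per_tone Occurrences of each tone `r`.
#' @return Expected percentage of adjacent pairs that repeat.
#' @export
analytic_repetition_pct <- function(n_tone_types, reps_per_tone) {
  stopifnot(n_tone_types >= 1, reps_per_tone >= 1)
  n <- n_tone_types * reps_per_tone
  if (n < 2) stop("need at least two tones in the block", call. = FALSE)
  100 * n_tone_types * reps_per_tone * (reps_per_tone - 1) / (n * (n - 1))
}

#' Simulate adjacent repetitions under complete randomization
#'
#' Draws `k_sims` uniformly random permutations of the block's tone
#' multiset and, for each, counts the fraction of the `N - 1` adjacent
#' pairs that carry the same tone. Quantifies how often a fully
#' randomized control condition would violate the no-repetition rule.
#'
#' @inheritParams analytic_repetition_pct
#' @param k_sims Number of simulated permutations.
#' @param seed Optional integer seed.
#' @return A list of class `"repsim_result"`: `mean_pct`, `sd_pct`,
#'   `se_pct` (simulation SE of the mean), `analytic_pct`, `k_sims`,
#'   and the spec.
#' @export
simulate_repetition_pct <- function(n_tone_types = 8, reps_per_tone = 180,
                                    k_sims = 10000, seed = NULL) {
  stopifnot(k_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  pool <- rep.int(seq_len(n_tone_types), reps_per_tone)
  n <- length(pool)
  if (n < 2) stop("need at least two tones in the block", call. = FALSE)
  pct <- vapply(seq_len(k_sims), function(i) {
    x <- sample(pool)
    100 * mean(x[-1] == x[-n])
  }, numeric(1))
  structure(
    list(mean_pct = mean(pct), sd_pct = stats::sd(pct),
         se_pct = stats::sd(pct) / sqrt(k_sims),
         analytic_pct = analytic_repetition_pct(n_tone_types, reps_per_tone),
         k_sims = as.integer(k_sims),
         n_tone_types = as.integer(n_tone_types),
         reps_per_tone = as.integer(reps_per_tone)),
    class = "repsim_result"
  )
}

#' @export
print.repsim_result <- function(x, ...) {
  cat(sprintf(
    "<repsim_result> %d tones x %d reps, k = %d: mean %.2f%% (SE %.3f), analytic %.2f%%\n",
    x$n_tone_types, x$reps_per_tone, x$k_sims, x$mean_pct, x$se_pct,
    x$analytic_pct
  ))
  invisible(x)
}
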