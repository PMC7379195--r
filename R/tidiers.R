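#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Bayes-factor result
#'
#' @param x A `bf_result`.
#' @param ... Unused.
#' @return A one-row tibble with the effect, prior, and Bayes factors.
#' @export
tidy.bf_result <- function(x, ...) {
  tibble::tibble(
    mean_diff = x$effect$mean_diff,
    se = x$effect$se,
    n = x$effect$n,
    prior = prior_label(x$prior),
    null_point = x$null_point,
    bf10 = x$bf10,
    bf01 = x$bf01,
    evidence = x$evidence_label
  )
}

#' @rdname tidy.bf_result
#' @export
glance.bf_result <- function(x, ...) {
  tibble::tibble(bf10 = x$bf10, bf01 = x$bf01,
                 integration_error = x$integration_error)
}

#' Tidy an amplitude summary
#'
#' @param x An `amplitude_summary`.
#' @param type `"contrasts"` (group contrasts with CIs),
#'   `"conditions"` (condition means), or `"subjects"` (per-subject
#'   contrasts, long).
#' @param ... Unused.
#' @export
tidy.amplitude_summary <- function(x, type = c("contrasts", "conditions",
                                               "subjects"), ...) {
  type <- match.arg(type)
  switch(type,
    contrasts = x$contrasts,
    conditions = x$condition_means,
    subjects = tidyr::pivot_longer(x$subject_contrasts, -"subject_id",
                                   names_to = "contrast",
                                   values_to = "value_uv")
  )
}

#' Tidy a synthetic-study result
#'
#' @param x An `mmn_study`.
#' @param ... Unused.
#' @return The Bayesian test table (`tidy`) or a one-row run summary
#'   (`glance`).
#' @export
tidy.mmn_study <- function(x, ...) x$bayes

#' @rdname tidy.mmn_study
#' @export
glance.mmn_study <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$config$n_subjects,
    n_retained = x$n_retained,
    n1_center_ms = x$windows$n1$center_ms,
    mmn_center_ms = x$windows$mmn$center_ms
  )
}

#' Tidy a repetition-simulation result
#'
#' @param x A `repsim_result`.
#' @param ... Unused.
#' @export
tidy.repsim_result <- function(x, ...) {
  tibble::tibble(
    n_tone_types = x$n_tone_types, reps_per_tone = x$reps_per_tone,
    k_sims = x$k_sims, mean_pct = x$mean_pct, sd_pct = x$sd_pct,
    se_pct = x$se_pct, analytic_pct = x$analytic_pct
  )
}
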