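#' An effect estimate feeding Bayesian inference
#'
#' A mean difference with its uncertainty, given either as a standard
#' error or as a symmetric 95% confidence interval (from which the SE is
#' recovered via the t distribution, see [se_from_ci()]).
#'
#' @param mean_diff Observed mean difference (microvolts in the ERP
#'   analyses, but any raw unit works).
#' @param n Number of subjects; degrees of freedom are `n - 1`.
#' @param ci Optional `c(lower, upper)` 95% CI.
#' @param se Optional standard error (exactly one of `ci`/`se`).
#' @return A list of class `"effect_estimate"`.
#' @export
effect_estimate <- function(mean_diff, n, ci = NULL, se = NULL) {
  stopifnot(n >= 2)
  if (is.null(se) == is.null(ci)) {
    stop("give exactly one of `ci` or `se`", call. = FALSE)
  }
  if (!is.null(ci)) {
    stopifnot(length(ci) == 2)
    se <- se_from_ci(ci[1], ci[2], n)
  }
  if (se <= 0) stop("se must be positive", call. = FALSE)
  structure(
    list(mean_diff = mean_diff, se = se, n = as.integer(n),
         df = as.integer(n) - 1L,
         ci_low = if (!is.null(ci)) ci[1] else NA_real_,
         ci_high = if (!is.null(ci)) ci[2] else NA_real_),
    class = "effect_estimate"
  )
}

#' Recover a standard error from a 95% confidence interval
#'
#' `se = (ci_high - ci_low) / (2 * t_{0.975, n-1})`, the inverse of the
#' usual t-based CI construction. Needed to consume published effect
#' estimates reported as mean and CI.
#'
#' @param ci_low,ci_high Interval bounds.
#' @param n Number of subjects.
#' @param level Confidence level of the interval.
#' @return The standard error.
#' @export
se_from_ci <- function(ci_low, ci_high, n, level = 0.95) {
  stopifnot(n >= 2)
  if (ci_high <= ci_low) stop("need ci_low < ci_high", call. = FALSE)
  (ci_high - ci_low) / (2 * stats::qt(1 - (1 - level) / 2, n - 1))
}

#' Prior models for the effect under the alternative hypothesis
#'
#' Informed priors on the raw effect size. The workhorse is the uniform
#' prior between zero (or a negative bound, for two-tailed analyses) and
#' an empirically motivated maximum. `point_prior()` at the null value
#' makes the alternative identical to the null (BF = 1), a useful
#' degenerate check. Normal and half-normal families are available for
#' robustness analyses.
#'
#' @param lower,upper Uniform bounds (`lower < upper`; equal bounds
#'   degenerate to a point prior).
#' @param location Point/normal location.
#' @param scale Normal/half-normal scale (> 0).
#' @return A list of class `"prior_spec"`.
#' @export
uniform_prior <- function(lower, upper) {
  if (lower > upper) stop("need lower <= upper", call. = FALSE)
  if (lower == upper) return(point_prior(lower))
  structure(list(family = "uniform", lower = lower, upper = upper),
            class = "prior_spec")
}

#' @rdname uniform_prior
#' @export
point_prior <- function(location) {
  structure(list(family = "point", location = location),
            class = "prior_spec")
}

#' @rdname uniform_prior
#' @export
normal_prior <- function(location, scale) {
  stopifnot(scale > 0)
  structure(list(family = "normal", location = location, scale = scale),
            class = "prior_spec")
}

#' @rdname uniform_prior
#' @export
half_normal_prior <- function(scale) {
  stopifnot(scale > 0)
  structure(list(family = "half_normal", scale = scale),
            class = "prior_spec")
}

prior_label <- function(prior) {
  switch(prior$family,
    uniform = sprintf("uniform[%g, %g]", prior$lower, prior$upper),
    point = sprintf("point(%g)", prior$location),
    normal = sprintf("normal(%g, %g)", prior$location, prior$scale),
    half_normal = sprintf("half-normal(%g)", prior$scale)
  )
}

# t-distributed likelihood of the data as a function of the true effect:
# a t density with df = n - 1, location at the observed mean, scale se.
effect_likelihood <- function(effect) {
  function(theta) {
    stats::dt((theta - effect$mean_diff) / effect$se, effect$df) / effect$se
  }
}

marginal_likelihood <- function(effect, prior, abs_tol = 1e-10) {
  lik <- effect_likelihood(effect)
  switch(prior$family,
    point = list(value = lik(prior$location), abs_error = 0),
    uniform = {
      q <- stats::integrate(lik, prior$lower, prior$upper,
                            rel.tol = 1e-10, abs.tol = abs_tol)
      list(value = q$value / (prior$upper - prior$lower),
           abs_error = q$abs.error / (prior$upper - prior$lower))
    },
    normal = {
      f <- function(th) lik(th) * stats::dnorm(th, prior$location, prior$scale)
      q <- stats::integrate(f, prior$location - 10 * prior$scale,
                            prior$location + 10 * prior$scale,
                            rel.tol = 1e-10, abs.tol = abs_tol)
      list(value = q$value, abs_error = q$abs.error)
    },
    half_normal = {
      f <- function(th) lik(th) * 2 * stats::dnorm(th, 0, prior$scale)
      q <- stats::integrate(f, 0, 10 * prior$scale,
                            rel.tol = 1e-10, abs.tol = abs_tol)
      list(value = q$value, abs_error = q$abs.error)
    }
  )
}

#' Bayes factor for a mean difference
#'
#' The likelihood of the data as a function of the true effect is a
#' shifted and scaled t density (df = `n - 1`, location = observed mean
#' difference, scale = SE). The Bayes factor in favour of the
#' alternative is the prior-averaged likelihood divided by the
#' likelihood at the null point:
#'
#'   BF10 = integral lik(theta) dPrior(theta) / lik(null_point),
#'
#' with `BF01 = 1 / BF10`. Integration is adaptive quadrature with
#' absolute tolerance below 1e-8.
#'
#' @param effect An [effect_estimate()].
#' @param prior A prior (see [uniform_prior()]).
#' @param null_point Null value of the effect.
#' @return A list of class `"bf_result"`: `bf10`, `bf01`,
#'   `evidence_label`, the inputs, and the integration error estimate.
#' @export
bf01 <- function(effect, prior, null_point = 0) {
  stopifnot(inherits(effect, "effect_estimate"), inherits(prior, "prior_spec"))
  lik <- effect_likelihood(effect)
  marg <- marginal_likelihood(effect, prior)
  lik0 <- lik(null_point)
  bf10 <- marg$value / lik0
  if (!is.finite(bf10)) stop("Bayes factor is not finite", call. = FALSE)
  structure(
    list(bf10 = bf10, bf01 = 1 / bf10,
         evidence_label = evidence_label(bf10),
         effect = effect, prior = prior, null_point = null_point,
         marginal_likelihood = marg$value, null_likelihood = lik0,
         integration_error = marg$abs_error),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf(
    "<bf_result> BF10 = %.4g, BF01 = %.4g (%s)\n  effect M = %g, SE = %g, n = %d; prior %s\n",
    x$bf10, x$bf01, x$evidence_label,
    x$effect$mean_diff, x$effect$se, x$effect$n, prior_label(x$prior)
  ))
  invisible(x)
}

#' Evidence category of a Bayes factor
#'
#' Conventional interpretation scheme applied to whichever direction
#' exceeds 1: 1-3 anecdotal, 3-10 moderate, 10-30 strong, 30-100 very
#' strong, >100 extreme evidence, labelled "for alternative" when
#' `bf10 > 1` and "for null" when `bf10 < 1`; `BF = 1` is
#' "no evidence".
#'
#' @param bf10 Bayes factor in favour of the alternative (a
#'   `bf_result` is also accepted).
#' @return A character label.
#' @export
evidence_label <- function(bf10) {
  if (inherits(bf10, "bf_result")) bf10 <- bf10$bf10
  stopifnot(bf10 > 0)
  if (bf10 == 1) return("no evidence")
  direction <- if (bf10 > 1) "for alternative" else "for null"
  b <- max(bf10, 1 / bf10)
  grade <- if (b < 3) "anecdotal" else if (b < 10) "moderate" else
    if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  paste(grade, "evidence", direction)
}

#' Robustness of a Bayes factor over alternative priors
#'
#' Evaluates the same effect against a list of candidate alternative
#' hypotheses, reporting one row per prior in the order given.
#'
#' @param effect An [effect_estimate()].
#' @param priors A list of priors.
#' @param null_point Null value.
#' @return A tibble: `prior`, `bf01`, `bf10`, `evidence`.
#' @export
robustness_grid <- function(effect, priors, null_point = 0) {
  stopifnot(length(priors) >= 1)
  purrr::map_dfr(priors, function(p) {
    r <- bf01(effect, p, null_point)
    tibble::tibble(prior = prior_label(p), bf01 = r$bf01, bf10 = r$bf10,
                   evidence = r$evidence_label)
  })
}
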