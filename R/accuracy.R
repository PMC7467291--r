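#' Sensitivity implied by an HSROC summary curve
#'
#' Hierarchical summary ROC (HSROC) meta-analyses summarise a diagnostic
#' test by an accuracy parameter (Lambda) and a shape parameter (beta). The
#' summary curve links the two operating characteristics by
#' `logit(sens) = Lambda * exp(-beta/2) - exp(-beta) * logit(spec)`.
#' This function evaluates the curve at a given specificity.
#'
#' @param specificity Specificity value(s), strictly inside (0, 1).
#' @param lambda HSROC accuracy parameter.
#' @param beta_shape HSROC shape parameter.
#' @return Sensitivity value(s) in (0, 1).
#' @examples
#' hsroc_sensitivity(0.7234, 3.156, -0.5362433) # ~0.923
#' @export
hsroc_sensitivity <- function(specificity, lambda, beta_shape) {
  if (any(specificity <= 0 | specificity >= 1)) {
    stop("`specificity` must be strictly inside (0, 1)", call. = FALSE)
  }
  inv_logit(lambda * exp(-beta_shape / 2) - exp(-beta_shape) * logit(specificity))
}

#' Jointly sample CT accuracy from HSROC summary parameters
#'
#' Specificity is sampled from a Beta distribution (method of moments from
#' its summary mean and standard error), the accuracy parameter Lambda from a
#' Normal distribution, and sensitivity is then computed from the HSROC curve
#' so the two operating characteristics move together. The shape parameter is
#' held constant. Degenerate (zero) standard errors return the summary-point
#' pair.
#'
#' @param params A list with elements `spec_mean`, `spec_se`, `lambda_mean`,
#'   `lambda_se`, `beta_shape`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return A tibble with columns `sensitivity` and `specificity`.
#' @export
sample_ct_accuracy <- function(params, n = 1, seed = NULL) {
  stopifnot(params$spec_mean > 0, params$spec_mean < 1, params$lambda_se >= 0,
            params$spec_se >= 0)
  if (!is.null(seed)) set.seed(seed)
  spec <- if (params$spec_se == 0) {
    rep(params$spec_mean, n)
  } else {
    mom <- beta_from_moments(params$spec_mean, params$spec_se)
    stats::rbeta(n, mom$alpha, mom$beta)
  }
  lambda <- stats::rnorm(n, params$lambda_mean, params$lambda_se)
  tibble::tibble(
    sensitivity = hsroc_sensitivity(spec, lambda, params$beta_shape),
    specificity = spec
  )
}

#' Convert a constant rate to a cumulative event probability
#'
#' Under a constant hazard, the probability of the event occurring within
#' `t` time units is `1 - exp(-rate * t)`.
#'
#' @param rate Non-negative rate per unit time.
#' @param t Non-negative elapsed time.
#' @return Probability in [0, 1).
#' @export
prob_from_rate <- function(rate, t) {
  if (any(rate < 0) || any(t < 0)) {
    stop("`rate` and `t` must be non-negative", call. = FALSE)
  }
  -expm1(-rate * t)
}

#' Monthly death probability from a mean survival time
#'
#' Assuming exponentially distributed survival with the given mean (in
#' months), the constant monthly death probability is
#' `1 - exp(-1 / mean_survival)`.
#'
#' @param mean_survival Mean survival in months, positive.
#' @return Monthly probability of death.
#' @examples
#' monthly_prob_from_mean_survival(36.7) # ~0.02688
#' @export
monthly_prob_from_mean_survival <- function(mean_survival) {
  if (any(mean_survival <= 0)) {
    stop("`mean_survival` must be positive", call. = FALSE)
  }
  -expm1(-1 / mean_survival)
}

#' Constant monthly probability matching a 12-month survival interval
#'
#' Given the surviving fractions at the start and end of a 12-month interval
#' of a survival curve, returns the constant monthly death probability that
#' reproduces the interval: `1 - (surv_end / surv_start)^(1/12)`.
#'
#' @param surv_start,surv_end Surviving proportions with
#'   `0 < surv_end <= surv_start <= 1`.
#' @return Monthly death probability.
#' @export
interval_monthly_prob <- function(surv_start, surv_end) {
  if (any(surv_end <= 0) || any(surv_end > surv_start) || any(surv_start > 1)) {
    stop("need 0 < surv_end <= surv_start <= 1", call. = FALSE)
  }
  1 - (surv_end / surv_start)^(1 / 12)
}

#' Maximum-likelihood exponential rate from fully observed event times
#'
#' For uncensored exponential data the ML estimate of the rate is the
#' reciprocal of the sample mean. Used to calibrate monthly progression
#' probabilities from observed nodule doubling times.
#'
#' @param event_times Positive event times (months), length >= 2.
#' @return The ML rate per month.
#' @export
fit_exponential_rate_ml <- function(event_times) {
  if (length(event_times) < 2 || any(!is.finite(event_times)) ||
      any(event_times <= 0)) {
    stop("`event_times` must be >= 2 positive finite times", call. = FALSE)
  }
  1 / mean(event_times)
}
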