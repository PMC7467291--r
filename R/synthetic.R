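#' Generate synthetic nodule doubling times
#'
#' Draws log-normal doubling times (months), emulating the right-skewed shape
#' of observed volume-doubling-time samples used to calibrate progression
#' rates. Values are synthetic; they reproduce a realistic distributional
#' shape, not any published data set.
#'
#' @param n Number of samples.
#' @param log_mean,log_sd Mean and standard deviation on the log scale.
#' @param seed Optional integer seed.
#' @return Numeric vector of positive times in months.
#' @export
generate_doubling_times <- function(n, log_mean = log(5.24), log_sd = 0.8,
                                    seed = NULL) {
  stopifnot(n >= 1, log_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  stats::rlnorm(n, meanlog = log_mean, sdlog = log_sd)
}
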