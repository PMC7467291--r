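#' Per-person expected value of perfect information
#'
#' The expected opportunity loss of deciding under current uncertainty:
#' the mean over PSA draws of the best achievable net monetary benefit,
#' minus the best strategy's mean net monetary benefit. Always non-negative.
#'
#' @param psa A `psa_result` with at least two strategies.
#' @param wtp Willingness-to-pay value(s).
#' @return Numeric vector of per-person EVPI (GBP), one per `wtp`.
#' @export
evpi_per_person <- function(psa, wtp) {
  if (length(psa$strategies) < 2) {
    stop("EVPI needs at least two strategies", call. = FALSE)
  }
  mats <- psa_matrices(psa)
  vapply(wtp, function(w) {
    nmb <- mats$qaly * w - mats$cost
    mean(apply(nmb, 1, max)) - max(colMeans(nmb))
  }, numeric(1))
}

psa_matrices <- function(psa) {
  res <- psa$results
  ord <- order(res$draw, match(res$strategy, psa$strategies))
  k <- length(psa$strategies)
  list(cost = matrix(res$cost[ord], ncol = k, byrow = TRUE),
       qaly = matrix(res$qaly[ord], ncol = k, byrow = TRUE))
}

#' Population scaling factor for value-of-information estimates
#'
#' The discounted number of patients who would benefit from resolved
#' uncertainty: `annual_incidence * sum_{t=0}^{horizon-1} (1 + discount)^-t`
#' (the first yearly cohort undiscounted).
#'
#' @param annual_incidence New patients per year.
#' @param horizon_years Years before the technology is superseded.
#' @param discount_annual Annual discount rate.
#' @return Effective discounted population size.
#' @examples
#' population_multiplier() # ~430,000 at 50,000/yr over 10 years at 3.5%
#' @export
population_multiplier <- function(annual_incidence = 50000,
                                  horizon_years = 10,
                                  discount_annual = 0.035) {
  stopifnot(annual_incidence > 0, horizon_years > 0, discount_annual >= 0)
  annual_incidence * sum((1 + discount_annual)^(-(seq_len(horizon_years) - 1)))
}

#' Default parameter groups for partial value-of-information analysis
#'
#' @return A named list of parameter-name vectors: disease-related mortality
#'   rates, initial patient characteristics (prevalence and stage mix), and
#'   utility values.
#' @export
parameter_groups <- function() {
  list(
    mortality_rates = c("mort_undiag_malig",
                        paste0("mort_distant_y", 1:4),
                        paste0("mort_local_y", 1:4),
                        paste0("mort_regional_y", 1:4)),
    initial_characteristics = c("prevalence", "stage_regional"),
    utility_values = c("u_age_55_64", "u_age_65_74", "u_age_75plus",
                       "u_local", "u_regional", "u_distant")
  )
}

#' Regression-based expected value of perfect parameter information
#'
#' Nonparametric-regression EVPPI: each strategy's net monetary benefit is
#' regressed on the group's sampled parameter values with an additive spline
#' smoother (a generalized additive model); the fitted values estimate the
#' conditional expected NMB given the group, and
#' `EVPPI = mean(max_s fitted) - max_s(mean fitted)`, truncated to the
#' feasible interval `[0, EVPI]`.
#' Estimates below twice their Monte-Carlo standard error are flagged as
#' indistinguishable from zero.
#'
#' @param psa A `psa_result` whose `$params` stores the sampled values.
#' @param group Character vector of parameter names (or the name of a group
#'   from [parameter_groups()]).
#' @param wtp Willingness-to-pay value(s).
#' @param k Spline basis dimension per parameter.
#' @return A tibble with columns `wtp`, `evppi`, `se`, `near_zero`.
#' @export
evppi_regression <- function(psa, group, wtp, k = 4) {
  if (length(group) == 1 && group %in% names(parameter_groups())) {
    group <- parameter_groups()[[group]]
  }
  missing_p <- setdiff(group, names(psa$params))
  if (length(missing_p) > 0) {
    stop("group parameter(s) not in PSA: ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  X <- psa$params[, group, drop = FALSE]
  keep <- vapply(X, function(x) stats::sd(x) > 0, logical(1))
  if (!any(keep)) {
    warning("all group parameters are constant across draws; EVPPI = 0")
    return(tibble::tibble(wtp = wtp, evppi = 0, se = 0, near_zero = TRUE))
  }
  X <- X[, keep, drop = FALSE]
  mats <- psa_matrices(psa)
  form <- stats::reformulate(sprintf("s(%s, k = %d)", names(X), k),
                             response = "nmb_y")
  purrr::map_dfr(wtp, function(w) {
    nmb <- mats$qaly * w - mats$cost
    evpi_w <- mean(apply(nmb, 1, max)) - max(colMeans(nmb))
    fitted <- apply(nmb, 2, function(y) {
      dat <- data.frame(nmb_y = y, X)
      stats::fitted(mgcv::gam(form, data = dat))
    })
    per_draw_max <- apply(fitted, 1, max)
    best <- which.max(colMeans(fitted))
    evppi <- mean(per_draw_max) - max(colMeans(fitted))
    loss <- per_draw_max - fitted[, best]
    se <- stats::sd(loss) / sqrt(length(loss))
    # partial information can never be worth more than perfect information;
    # truncate regression/smoothing noise to the feasible interval
    evppi <- min(max(evppi, 0), evpi_w)
    tibble::tibble(wtp = w, evppi = evppi, se = se,
                   near_zero = evppi <= 2 * se)
  })
}

#' Value-of-information summary table
#'
#' Per-person and population EVPI over a willingness-to-pay grid, plus
#' population EVPPI for each parameter group at a reference
#' willingness-to-pay.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Willingness-to-pay grid for the EVPI curve.
#' @param wtp_ref Reference willingness-to-pay for the group EVPPIs.
#' @param groups Named list of parameter groups.
#' @param pop Population multiplier (see [population_multiplier()]).
#' @return A list with `evpi` (tibble: wtp, evpi_per_person, evpi_population)
#'   and `evppi` (tibble: group, wtp, evppi_per_person, evppi_population,
#'   se, near_zero).
#' @export
voi_summary <- function(psa, wtp_grid = seq(0, 50000, by = 2500),
                        wtp_ref = 20000, groups = parameter_groups(),
                        pop = population_multiplier()) {
  evpi_pp <- evpi_per_person(psa, wtp_grid)
  evpi <- tibble::tibble(wtp = wtp_grid, evpi_per_person = evpi_pp,
                         evpi_population = evpi_pp * pop)
  evppi <- purrr::imap_dfr(groups, function(g, nm) {
    evppi_regression(psa, g, wtp_ref) |>
      dplyr::mutate(group = nm, .before = 1) |>
      dplyr::rename(evppi_per_person = "evppi") |>
      dplyr::mutate(evppi_population = .data$evppi_per_person * pop)
  })
  list(evpi = evpi, evppi = evppi)
}
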