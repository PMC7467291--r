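#' Model run configuration
#'
#' Collects the run-level settings of the model: which AABT accuracy scenario
#' to use, test price, willingness-to-pay, discounting, cohort age and the CT
#' surveillance schedule.
#'
#' @param scenario AABT accuracy scenario: `"A"` (sensitivity 0.41,
#'   specificity 0.93) or `"B"` (sensitivity 0.28, specificity 0.98).
#' @param test_price AABT price in GBP.
#' @param wtp Willingness-to-pay per QALY in GBP.
#' @param discount_annual Annual discount rate for costs and outcomes.
#' @param start_age Cohort age at entry, years.
#' @param max_age Age at which the lifetime horizon is truncated.
#' @param scan_months CT surveillance schedule (months after entry).
#' @param undiag_cancer_utilities Use stage-specific cancer utilities in
#'   undiagnosed malignant states (capped by the age norm); if `FALSE`,
#'   undiagnosed patients carry the age-norm utility.
#' @param immediate_ct_detection Apply CT sensitivity to undiagnosed
#'   malignant nodules at every scheduled scan; if `FALSE`, malignancy is only
#'   detectable from the second scan onwards (a proxy for requiring an
#'   observed doubling event first).
#' @param pm50_on_rate Interpret +/-50% uncertainty ranges on the rate scale
#'   (see [draw_parameter_set()]).
#' @return A list with class `"ipn_config"`.
#' @export
scenario_config <- function(scenario = c("A", "B"),
                            test_price = 70,
                            wtp = 20000,
                            discount_annual = 0.035,
                            start_age = 62,
                            max_age = 100,
                            scan_months = c(3, 12, 24),
                            undiag_cancer_utilities = TRUE,
                            immediate_ct_detection = TRUE,
                            pm50_on_rate = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(discount_annual >= 0, test_price >= 0, wtp >= 0,
            max_age > start_age, all(diff(scan_months) > 0))
  structure(list(
    scenario = scenario,
    test_price = test_price,
    wtp = wtp,
    discount_annual = discount_annual,
    start_age = start_age,
    max_age = max_age,
    scan_months = scan_months,
    undiag_cancer_utilities = undiag_cancer_utilities,
    immediate_ct_detection = immediate_ct_detection,
    pm50_on_rate = pm50_on_rate,
    tunnel_months = 60L,
    distant_tunnel_months = 48L
  ), class = "ipn_config")
}

#' AABT accuracy for a named scenario
#'
#' @param scenario `"A"` or `"B"`.
#' @return A list with `sensitivity` and `specificity`.
#' @export
aabt_accuracy <- function(scenario = c("A", "B")) {
  scenario <- match.arg(scenario)
  if (scenario == "A") list(sensitivity = 0.41, specificity = 0.93)
  else list(sensitivity = 0.28, specificity = 0.98)
}

n_cycles <- function(config) (config$max_age - config$start_age) * 12L
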