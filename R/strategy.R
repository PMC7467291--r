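# The two testing pathways wired onto the cohort engine:
#   Surveillance      — CT scans at 3, 12 and 24 months, then discharge.
#   AABT+Surveillance — upfront autoantibody test; positives go to MDT +
#                       guided needle biopsy (surgery if malignant);
#                       negatives follow the surveillance schedule.

#' Expected outcome of surgery (or surgical biopsy)
#'
#' For a malignant nodule: thoracic surgery with its complication mix plus
#' expected adjuvant radiotherapy/chemotherapy, and surgery-related mortality.
#' For a benign nodule (surgical biopsy after observed growth): the surgical
#' biopsy tariff with its complication mix and its own mortality.
#'
#' @param malignant Logical.
#' @param params An `ipn_params` parameter set.
#' @return A list with `expected_cost` (GBP) and `mortality`.
#' @export
expected_surgery_outcome <- function(malignant, params) {
  if (malignant) {
    comp <- pval(params, "comp_surgery_malig")
    list(
      expected_cost =
        (1 - comp) * pval(params, "cost_surgery_nocomp") +
        comp * pval(params, "cost_surgery_comp") +
        pval(params, "prop_radiotherapy") * pval(params, "cost_radiotherapy") +
        pval(params, "prop_chemotherapy") * pval(params, "cost_chemotherapy"),
      mortality = pval(params, "mort_surgery_malig")
    )
  } else {
    comp <- pval(params, "comp_surgery_benign")
    list(
      expected_cost =
        (1 - comp) * pval(params, "cost_surgical_biopsy_nocomp") +
        comp * pval(params, "cost_surgical_biopsy_comp"),
      mortality = pval(params, "mort_surgery_benign")
    )
  }
}

# cohort composition at presentation, before any testing
initial_distribution <- function(params) {
  prev <- pval(params, "prevalence")
  c(ub_ng = 1 - prev,
    ul = prev * pval(params, "stage_local"),
    ur = prev * pval(params, "stage_regional"))
}

#' Apply the upfront AABT decision tree to the presenting cohort
#'
#' Splits the presenting cohort (prevalence of malignancy, local/regional
#' stage mix) by the autoantibody test result. Positives incur MDT review and
#' a guided needle biopsy (with its mortality and serious-adverse-event
#' decrement); biopsy-confirmed malignancies proceed to surgery and enter the
#' diagnosed tunnel states; false positives return to surveillance; negatives
#' enter surveillance untouched. Everyone tested incurs the test price.
#'
#' @param params An `ipn_params` parameter set.
#' @param test A list with `sensitivity` and `specificity` for the AABT.
#' @param config A [scenario_config()]; supplies the test price.
#' @return A list: `state` (named distribution over model states including
#'   upfront deaths), `cost` (expected upfront cost per presenting patient),
#'   `qaly_adj` (one-off QALY decrement), `label`.
#' @export
apply_initial_test_split <- function(params, test, config = scenario_config()) {
  stopifnot(test$sensitivity >= 0, test$sensitivity <= 1,
            test$specificity >= 0, test$specificity <= 1)
  init <- initial_distribution(params)
  benign <- init[["ub_ng"]]; mal_l <- init[["ul"]]; mal_r <- init[["ur"]]

  sens <- test$sensitivity; spec <- test$specificity
  tp_l <- mal_l * sens; tp_r <- mal_r * sens
  fn_l <- mal_l * (1 - sens); fn_r <- mal_r * (1 - sens)
  fp <- benign * (1 - spec); tn <- benign * spec
  pos <- tp_l + tp_r + fp

  mb <- pval(params, "mort_biopsy")
  sae <- pval(params, "biopsy_complication")
  d_sae <- pval(params, "u_biopsy_sae_decrement") / 12
  surg <- expected_surgery_outcome(TRUE, params)

  cost <- config$test_price +
    pos * (pval(params, "cost_mdt") + pval(params, "cost_needle_biopsy")) +
    (tp_l + tp_r) * (1 - mb) * surg$expected_cost
  qaly_adj <- -pos * (1 - mb) * sae * d_sae

  dead <- pos * mb + (tp_l + tp_r) * (1 - mb) * surg$mortality
  state <- c(
    ub_ng = tn + fp * (1 - mb),
    ul = fn_l, ur = fn_r,
    dl_m1 = tp_l * (1 - mb) * (1 - surg$mortality),
    dr_m1 = tp_r * (1 - mb) * (1 - surg$mortality),
    dead = dead
  )
  if (abs(sum(state) - 1) > 1e-12) {
    stop("internal error: initial test split does not sum to 1", call. = FALSE)
  }
  list(state = state, cost = cost, qaly_adj = qaly_adj, label = "aabt_test")
}

#' Surveillance CT scan event
#'
#' Applies one scheduled CT scan to the under-surveillance states of a cohort
#' vector. Every under-surveillance patient incurs the CT tariff. Benign
#' nodules whose growth flag has fired are referred for surgical biopsy
#' (growth detection is taken as perfectly accurate) and move to diagnosed
#' benign if they survive. Undiagnosed malignant nodules are detected with CT
#' sensitivity and proceed through MDT, guided needle biopsy and surgery into
#' the diagnosed tunnel states. Non-grown benign nodules generate CT false
#' positives at `1 - specificity`, leading to a guided needle biopsy (benign,
#' so back to surveillance).
#'
#' @param v Named state vector (occupancy at the scan month).
#' @param params An `ipn_params` parameter set.
#' @param config A [scenario_config()].
#' @param detect_malignant Whether CT sensitivity is applied to undiagnosed
#'   malignant nodules at this scan (see `immediate_ct_detection`).
#' @return A list: `state`, `cost`, `qaly_adj`, `label`.
#' @export
surveillance_scan_event <- function(v, params, config = scenario_config(),
                                    detect_malignant = TRUE) {
  ct_sens <- pval(params, "ct_sens"); ct_spec <- pval(params, "ct_spec")
  mb <- pval(params, "mort_biopsy")
  sae <- pval(params, "biopsy_complication")
  d_sae <- pval(params, "u_biopsy_sae_decrement") / 12

  scanned <- v[["ub_ng"]] + v[["ub_g"]] + v[["ul"]] + v[["ur"]] + v[["ud"]]
  cost <- pval(params, "cost_ct") * scanned
  qaly_adj <- 0

  # grown benign -> surgical biopsy -> diagnosed benign
  surg_b <- expected_surgery_outcome(FALSE, params)
  grown <- v[["ub_g"]]
  cost <- cost + grown * surg_b$expected_cost
  v[["db"]] <- v[["db"]] + grown * (1 - surg_b$mortality)
  v[["dead"]] <- v[["dead"]] + grown * surg_b$mortality
  v[["ub_g"]] <- 0

  # CT false positives on non-grown benign -> guided needle biopsy -> back
  fp <- v[["ub_ng"]] * (1 - ct_spec)
  cost <- cost + fp * pval(params, "cost_needle_biopsy")
  qaly_adj <- qaly_adj - fp * (1 - mb) * sae * d_sae
  v[["dead"]] <- v[["dead"]] + fp * mb
  v[["ub_ng"]] <- v[["ub_ng"]] - fp * mb

  # undiagnosed malignant detected -> MDT + needle biopsy -> surgery
  if (detect_malignant) {
    surg_m <- expected_surgery_outcome(TRUE, params)
    dest <- c(ul = "dl_m1", ur = "dr_m1", ud = "dd_m1")
    for (s in names(dest)) {
      det <- v[[s]] * ct_sens
      if (det == 0) next
      cost <- cost + det * (pval(params, "cost_mdt") + pval(params, "cost_needle_biopsy"))
      qaly_adj <- qaly_adj - det * (1 - mb) * sae * d_sae
      surv_b <- det * (1 - mb)
      cost <- cost + surv_b * surg_m$expected_cost
      v[[dest[[s]]]] <- v[[dest[[s]]]] + surv_b * (1 - surg_m$mortality)
      v[["dead"]] <- v[["dead"]] + det * mb + surv_b * surg_m$mortality
      v[[s]] <- v[[s]] * (1 - ct_sens)
    }
  }
  list(state = v, cost = cost, qaly_adj = qaly_adj, label = "ct_scan")
}

# assemble the event schedule for a strategy
strategy_events <- function(strategy, params, config, test) {
  events <- list()
  if (strategy == "aabt") {
    events[["0"]] <- function(v, params, config) {
      out <- apply_initial_test_split(params, test, config)
      full <- v * 0
      full[names(out$state)] <- out$state
      out$state <- full
      out
    }
  }
  for (k in seq_along(config$scan_months)) {
    t <- config$scan_months[k]
    detect <- config$immediate_ct_detection || k > 1
    events[[as.character(t)]] <- local({
      d <- detect
      function(v, params, config) surveillance_scan_event(v, params, config,
                                                          detect_malignant = d)
    })
  }
  events
}

#' Evaluate one testing strategy over the lifetime horizon
#'
#' Combines the upfront decision tree (AABT arm), the scheduled surveillance
#' scans and the Markov cohort engine into lifetime discounted cost and QALYs
#' for one strategy under one parameter set.
#'
#' @param params An `ipn_params` parameter set (see [draw_parameter_set()]).
#' @param strategy `"surveillance"` or `"aabt"`.
#' @param config A [scenario_config()].
#' @param life_table A life table tibble.
#' @param test AABT accuracy; defaults to the config scenario's pair.
#' @param matrices Optional precomputed transition-matrix set (internal
#'   reuse across strategies).
#' @param keep_trace Keep the full cohort trace on the result.
#' @return An object of class `"strategy_result"` with elements `strategy`,
#'   `cost`, `qaly`, `cost_undisc`, `qaly_undisc` and optionally `trace`.
#' @examples
#' params <- draw_parameter_set(ipn_parameters())
#' res <- evaluate_strategy(params, "surveillance")
#' tidy(res)
#' @export
evaluate_strategy <- function(params, strategy = c("surveillance", "aabt"),
                              config = scenario_config(),
                              life_table = gompertz_life_table(max_age = config$max_age),
                              test = aabt_accuracy(config$scenario),
                              matrices = NULL, keep_trace = FALSE) {
  strategy <- match.arg(strategy)
  events <- strategy_events(strategy, params, config, test)
  trace <- run_cohort(initial_distribution(params), params, config, life_table,
                      events = events, matrices = matrices)
  out <- accumulate_outcomes(trace, params, config)
  structure(list(
    strategy = strategy,
    cost = out$cost, qaly = out$qaly,
    cost_undisc = out$cost_undisc, qaly_undisc = out$qaly_undisc,
    test = if (strategy == "aabt") test else NULL,
    config = config,
    trace = if (keep_trace) trace else NULL
  ), class = "strategy_result")
}

#' Evaluate several strategies under a common parameter set
#'
#' @inheritParams evaluate_strategy
#' @param strategies Character vector of strategy labels; `"surveillance"`,
#'   `"aabt_A"`, `"aabt_B"` (or `"aabt"`, which uses the config scenario).
#' @return A tibble with one row per strategy (`strategy`, `cost`, `qaly`).
#' @export
evaluate_strategies <- function(params,
                                strategies = c("surveillance", "aabt"),
                                config = scenario_config(),
                                life_table = gompertz_life_table(max_age = config$max_age),
                                matrices = NULL) {
  if (is.null(matrices)) {
    matrices <- transition_matrix_set(params, life_table, config)
  }
  purrr::map_dfr(strategies, function(s) {
    kind <- if (s == "surveillance") "surveillance" else "aabt"
    test <- switch(s,
      surveillance = NULL,
      aabt = aabt_accuracy(config$scenario),
      aabt_A = aabt_accuracy("A"),
      aabt_B = aabt_accuracy("B"),
      stop("unknown strategy label: ", s, call. = FALSE)
    )
    res <- evaluate_strategy(params, kind, config, life_table,
                             test = if (is.null(test)) aabt_accuracy(config$scenario) else test,
                             matrices = matrices)
    tibble::tibble(strategy = s, cost = res$cost, qaly = res$qaly,
                   cost_undisc = res$cost_undisc, qaly_undisc = res$qaly_undisc)
  })
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result> %s: cost £%.2f, QALYs %.4f (discounted)\n",
              x$strategy, x$cost, x$qaly))
  invisible(x)
}

#' Tidy a strategy result
#'
#' @param x A `strategy_result`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy strategy_result
#' @export
tidy.strategy_result <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, cost = x$cost, qaly = x$qaly,
                 cost_undisc = x$cost_undisc, qaly_undisc = x$qaly_undisc)
}
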