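#' Net monetary benefit
#'
#' `NMB = QALYs * WTP - cost`, per strategy at a given willingness-to-pay.
#'
#' @param result A `strategy_result`, or a data frame with `cost` and `qaly`
#'   columns.
#' @param wtp Willingness-to-pay per QALY (GBP), non-negative.
#' @return Numeric vector of NMB values (GBP).
#' @export
compute_nmb <- function(result, wtp) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  if (inherits(result, "strategy_result")) {
    result$qaly * wtp - result$cost
  } else if (is.data.frame(result)) {
    result$qaly * wtp - result$cost
  } else {
    stop("`result` must be a strategy_result or a data frame with cost/qaly",
         call. = FALSE)
  }
}

#' Incremental cost-effectiveness comparison of two strategies
#'
#' Computes incremental cost, incremental QALYs and the ICER of a comparator
#' against a reference. When the comparator is cheaper and more effective it
#' `"dominates"`; more costly and less effective, it is `"dominated"`; equal
#' QALYs with a cost difference gives an infinite ICER.
#'
#' @param ref,comp `strategy_result` objects (reference and comparator), or
#'   one-row data frames with `cost` and `qaly`.
#' @param wtp Willingness-to-pay used for the NMB columns.
#' @return An object of class `"ce_comparison"`; see [tidy.ce_comparison()].
#' @export
compute_icer <- function(ref, comp, wtp = 20000) {
  as_row <- function(x, default_name) {
    if (inherits(x, "strategy_result")) {
      tibble::tibble(strategy = x$strategy, cost = x$cost, qaly = x$qaly)
    } else {
      tibble::tibble(strategy = x$strategy %||% default_name,
                     cost = x$cost, qaly = x$qaly)
    }
  }
  r <- as_row(ref, "reference"); c_ <- as_row(comp, "comparator")
  stopifnot(is.finite(r$cost), is.finite(r$qaly),
            is.finite(c_$cost), is.finite(c_$qaly))
  dc <- c_$cost - r$cost
  dq <- c_$qaly - r$qaly
  if (dq == 0) {
    icer <- if (dc == 0) NA_real_ else Inf
    label <- NA_character_
  } else if (dc <= 0 && dq > 0) {
    icer <- NA_real_; label <- "dominates"
  } else if (dc >= 0 && dq < 0) {
    icer <- NA_real_; label <- "dominated"
  } else {
    icer <- dc / dq; label <- NA_character_
  }
  structure(list(
    reference = r, comparator = c_,
    delta_cost = dc, delta_qaly = dq,
    icer = icer, dominance = label, wtp = wtp,
    nmb_reference = r$qaly * wtp - r$cost,
    nmb_comparator = c_$qaly * wtp - c_$cost
  ), class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  lab <- if (!is.na(x$dominance)) x$dominance
         else if (is.na(x$icer)) "identical"
         else sprintf("ICER £%.0f/QALY", x$icer)
  cat(sprintf("<ce_comparison> %s vs %s: dC £%.2f, dQ %.4f -> %s\n",
              x$comparator$strategy, x$reference$strategy,
              x$delta_cost, x$delta_qaly, lab))
  invisible(x)
}

#' Tidy an incremental comparison
#'
#' @param x A `ce_comparison`.
#' @param ... Unused.
#' @return A two-row tibble mirroring the standard results-table layout
#'   (total cost, incremental cost, QALYs, incremental QALYs, ICER, NMB).
#' @method tidy ce_comparison
#' @export
tidy.ce_comparison <- function(x, ...) {
  tibble::tibble(
    strategy = c(x$reference$strategy, x$comparator$strategy),
    cost = c(x$reference$cost, x$comparator$cost),
    inc_cost = c(NA_real_, x$delta_cost),
    qaly = c(x$reference$qaly, x$comparator$qaly),
    inc_qaly = c(NA_real_, x$delta_qaly),
    icer = c(NA_real_, x$icer),
    dominance = c(NA_character_, x$dominance),
    nmb = c(x$nmb_reference, x$nmb_comparator)
  )
}

#' Multi-strategy comparison on the efficiency frontier
#'
#' Orders strategies by effectiveness, removes strictly dominated strategies
#' (more costly, no more effective) and extendedly dominated ones (a higher
#' sequential ICER than the next strategy up the frontier), and reports
#' sequential ICERs between adjacent frontier members.
#'
#' @param results A data frame with columns `strategy`, `cost`, `qaly`.
#' @param wtp Willingness-to-pay for the NMB column.
#' @return A tibble sorted by QALYs with `inc_cost`, `inc_qaly`, `icer`
#'   (sequential, frontier members only), `status` and `nmb`.
#' @export
compare_strategies <- function(results, wtp = 20000) {
  stopifnot(all(c("strategy", "cost", "qaly") %in% names(results)))
  tab <- dplyr::arrange(tibble::as_tibble(results), .data$qaly, .data$cost)
  tab$status <- "frontier"
  # strict dominance
  repeat {
    changed <- FALSE
    onf <- which(tab$status == "frontier")
    for (i in onf) {
      others <- setdiff(onf, i)
      if (any(tab$cost[others] <= tab$cost[i] & tab$qaly[others] >= tab$qaly[i] &
              (tab$cost[others] < tab$cost[i] | tab$qaly[others] > tab$qaly[i]))) {
        tab$status[i] <- "dominated"; changed <- TRUE
      }
    }
    if (!changed) break
  }
  # extended dominance: sequential ICERs must be increasing in qaly order
  repeat {
    onf <- which(tab$status == "frontier")
    if (length(onf) < 3) break
    icers <- diff(tab$cost[onf]) / diff(tab$qaly[onf])
    bad <- which(diff(icers) < 0)
    if (length(bad) == 0) break
    tab$status[onf[bad[1] + 1]] <- "ext_dominated"
  }
  onf <- which(tab$status == "frontier")
  tab$inc_cost <- NA_real_; tab$inc_qaly <- NA_real_; tab$icer <- NA_real_
  if (length(onf) > 1) {
    tab$inc_cost[onf[-1]] <- diff(tab$cost[onf])
    tab$inc_qaly[onf[-1]] <- diff(tab$qaly[onf])
    tab$icer[onf[-1]] <- tab$inc_cost[onf[-1]] / tab$inc_qaly[onf[-1]]
  }
  tab$nmb <- tab$qaly * wtp - tab$cost
  tab
}

#' Threshold price of the AABT
#'
#' The price at which the AABT strategy's net monetary benefit equals that of
#' surveillance alone. Because every presenting patient is tested exactly
#' once at model entry (undiscounted), total AABT-arm cost is linear in the
#' price with slope 1, giving the closed form
#' `p* = p0 + (dQ * wtp - dC(p0))`. A bisection on the full model is run as
#' an independent check; the two must agree to £0.01.
#'
#' @param params An `ipn_params` parameter set.
#' @param config A [scenario_config()]; `config$test_price` is the anchor
#'   price `p0`.
#' @param life_table A life table tibble.
#' @param wtp Willingness-to-pay per QALY.
#' @param method `"closed_form"`, `"bisection"`, or `"both"` (checks
#'   agreement).
#' @param bracket Price bracket for the bisection.
#' @param tol Bisection tolerance in GBP.
#' @return The threshold price in GBP.
#' @export
threshold_price <- function(params, config = scenario_config(),
                            life_table = gompertz_life_table(max_age = config$max_age),
                            wtp = config$wtp, method = c("both", "closed_form", "bisection"),
                            bracket = c(0, 10000), tol = 0.005) {
  method <- match.arg(method)
  matrices <- transition_matrix_set(params, life_table, config)
  surv <- evaluate_strategy(params, "surveillance", config, life_table,
                            matrices = matrices)
  eval_at <- function(p) {
    cfg <- config; cfg$test_price <- p
    evaluate_strategy(params, "aabt", cfg, life_table, matrices = matrices)
  }
  aabt0 <- eval_at(config$test_price)
  dq <- aabt0$qaly - surv$qaly
  dc0 <- aabt0$cost - surv$cost
  closed <- config$test_price + (dq * wtp - dc0)
  if (method == "closed_form") return(closed)

  f <- function(p) compute_nmb(eval_at(p), wtp) - compute_nmb(surv, wtp)
  lo <- bracket[1]; hi <- bracket[2]
  if (f(lo) < 0 || f(hi) > 0) {
    stop("bisection bracket does not contain the threshold price", call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  bisect <- (lo + hi) / 2
  if (method == "bisection") return(bisect)
  if (abs(bisect - closed) > 0.01) {
    stop(sprintf("threshold price mismatch: closed form £%.4f vs bisection £%.4f",
                 closed, bisect), call. = FALSE)
  }
  closed
}
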