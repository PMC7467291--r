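#' Probabilistic sensitivity analysis
#'
#' Samples parameter sets from the registry's uncertainty distributions and
#' evaluates every strategy under each draw with common random parameters
#' (one parameter set per draw shared across strategies), so incremental
#' costs and QALYs are coherent within a draw.
#'
#' @param defs Parameter registry tibble (see [ipn_parameters()]).
#' @param config A [scenario_config()].
#' @param n_draws Number of parameter draws.
#' @param seed Integer seed for the whole run.
#' @param strategies Strategy labels passed to [evaluate_strategies()];
#'   use `c("surveillance", "aabt_A", "aabt_B")` for a three-way analysis.
#' @param life_table A life table tibble.
#' @param probabilistic If `FALSE`, a single base-case evaluation per
#'   strategy is returned (useful for smoke checks).
#' @return An object of class `"psa_result"`: `$results` (tibble of draw,
#'   strategy, cost, qaly), `$params` (tibble of sampled parameter values per
#'   draw), `$seed`, `$n_resampled`.
#' @export
run_psa <- function(defs, config = scenario_config(), n_draws = 1000,
                    seed = 1L,
                    strategies = c("surveillance", "aabt"),
                    life_table = gompertz_life_table(max_age = config$max_age),
                    probabilistic = TRUE) {
  stopifnot(n_draws >= 1)
  param_tbl <- draw_parameter_sets(defs, n_draws, seed = seed,
                                   probabilistic = probabilistic,
                                   pm50_on_rate = config$pm50_on_rate)
  # validity guard: every probability-typed value must be a probability.
  prob_names <- defs$name[defs$units %in% c("probability/month",
                                            "probability/event",
                                            "proportion", "utility")]
  n_resampled <- 0L
  repeat {
    vals <- as.matrix(param_tbl[, prob_names])
    bad <- which(rowSums(vals < 0 | vals > 1) > 0)
    if (length(bad) == 0) break
    message("resampling ", length(bad), " invalid parameter draw(s)")
    n_resampled <- n_resampled + length(bad)
    for (b in bad) {
      ps <- draw_parameter_set(defs, seed = NULL, probabilistic = TRUE,
                               pm50_on_rate = config$pm50_on_rate, draw_id = b)
      param_tbl[b, names(ps)] <- tibble::as_tibble(unclass(ps))
    }
  }
  results <- purrr::map_dfr(seq_len(n_draws), function(i) {
    params <- params_from_row(param_tbl[i, ])
    evaluate_strategies(params, strategies, config, life_table) |>
      dplyr::mutate(draw = i, .before = 1)
  })
  structure(list(
    results = results[, c("draw", "strategy", "cost", "qaly")],
    params = param_tbl,
    strategies = strategies,
    config = config,
    seed = seed,
    n_draws = n_draws,
    n_resampled = n_resampled
  ), class = "psa_result")
}

# one row of a sampled parameter table -> ipn_params
params_from_row <- function(row) {
  p <- as.list(row)
  p$draw <- NULL
  structure(p, class = "ipn_params",
            draw_id = row$draw %||% NA_integer_, probabilistic = TRUE)
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n_draws, "draws x",
      length(x$strategies), "strategies (seed", paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Tidy PSA results
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return The per-draw results tibble (`draw`, `strategy`, `cost`, `qaly`).
#' @method tidy psa_result
#' @export
tidy.psa_result <- function(x, ...) x$results

#' Summarise a PSA against a reference strategy
#'
#' @param x A `psa_result`.
#' @param ref Reference strategy label.
#' @param ... Unused.
#' @return A one-row-per-comparator tibble with mean increments and the
#'   probabilities of being more costly / more effective than the reference.
#' @method glance psa_result
#' @export
glance.psa_result <- function(x, ref = "surveillance", ...) {
  wide_c <- tidyr::pivot_wider(x$results, id_cols = "draw",
                               names_from = "strategy",
                               values_from = c("cost", "qaly"))
  comps <- setdiff(x$strategies, ref)
  purrr::map_dfr(comps, function(s) {
    dc <- wide_c[[paste0("cost_", s)]] - wide_c[[paste0("cost_", ref)]]
    dq <- wide_c[[paste0("qaly_", s)]] - wide_c[[paste0("qaly_", ref)]]
    tibble::tibble(
      comparator = s, reference = ref, n_draws = x$n_draws,
      mean_inc_cost = mean(dc), mean_inc_qaly = mean(dq),
      p_more_costly = mean(dc > 0), p_more_effective = mean(dq > 0)
    )
  })
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability (over PSA draws) that
#' each strategy has the highest net monetary benefit. Ties are split evenly
#' among the tied strategies, so probabilities sum to one at every point.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty numeric vector of willingness-to-pay values.
#' @return A tibble with columns `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0) stop("`wtp_grid` must be non-empty", call. = FALSE)
  res <- psa$results
  strategies <- psa$strategies
  cost <- matrix(res$cost[order(res$draw, match(res$strategy, strategies))],
                 ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(res$qaly[order(res$draw, match(res$strategy, strategies))],
                 ncol = length(strategies), byrow = TRUE)
  purrr::map_dfr(wtp_grid, function(w) {
    nmb <- qaly * w - cost
    best <- nmb == apply(nmb, 1, max)
    weight <- best / rowSums(best)
    tibble::tibble(wtp = w, strategy = strategies,
                   probability = colMeans(weight))
  })
}
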