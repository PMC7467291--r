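#' Monte-Carlo micro-simulation of the cohort natural history
#'
#' Simulates a finite cohort of individuals through the same cycle-specific
#' transition matrices as [run_cohort()], by multinomial sampling of each
#' state's occupants every cycle. Used as an independent stochastic oracle
#' for the deterministic cohort trace; scheduled testing events are not
#' applied here (they are verified against closed-form probability trees).
#'
#' @param initial Named initial distribution over model states (sums to 1).
#' @param params An `ipn_params` parameter set.
#' @param config A [scenario_config()].
#' @param life_table A life table tibble.
#' @param n_individuals Cohort size.
#' @param n_cycles Number of cycles to simulate.
#' @param seed Optional integer seed.
#' @return A matrix (cycles + 1 by states) of occupancy proportions.
#' @export
simulate_cohort_multinomial <- function(initial, params,
                                        config = scenario_config(),
                                        life_table = gompertz_life_table(max_age = config$max_age),
                                        n_individuals = 50000,
                                        n_cycles = 240, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- model_states(config)
  S <- nrow(states)
  cnt <- stats::setNames(integer(S), states$state)
  alloc <- stats::rmultinom(1, n_individuals,
                            prob = {
                              v <- stats::setNames(numeric(S), states$state)
                              v[names(initial)] <- initial
                              v
                            })[, 1]
  cnt[] <- alloc
  matrices <- transition_matrix_set(params, life_table, config)
  occ <- matrix(0, n_cycles + 1, S, dimnames = list(0:n_cycles, states$state))
  occ[1, ] <- cnt / n_individuals
  for (t in seq_len(n_cycles)) {
    M <- matrices$mats[[matrices$idx[t]]]
    newc <- integer(S)
    for (s in which(cnt > 0)) {
      newc <- newc + stats::rmultinom(1, cnt[s], M[s, ])[, 1]
    }
    cnt <- newc
    occ[t + 1, ] <- cnt / n_individuals
  }
  occ
}
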