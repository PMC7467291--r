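test_that("transition matrices are row-stochastic at every cycle", {
  ms <- nodulecea:::transition_matrix_set(base_params, base_lt, base_cfg)
  for (M in ms$mats) {
    expect_true(all(abs(rowSums(M) - 1) < 1e-9))
    expect_true(all(M >= 0))
  }
  # derived age matrices agree with the reference single-cycle builder
  for (cyc in c(1, 2, 13, 120, 456)) {
    expect_equal(ms$mats[[ms$idx[cyc]]],
                 build_transition_matrix(base_params, cyc, base_lt, base_cfg),
                 tolerance = 1e-12)
  }
})

test_that("within-cycle event ordering composes progression then mortality", {
  M <- build_transition_matrix(base_params, 2, zero_lt, base_cfg)
  p <- base_params$prob_progression
  m <- base_params$mort_undiag_malig
  # brute-force enumeration of the one-cycle event tree from undiag local:
  # progress (p), then excess death (m); background off
  expect_equal(M["ul", "ur"], p * (1 - m), tolerance = 1e-12)
  expect_equal(M["ul", "ul"], (1 - p) * (1 - m), tolerance = 1e-12)
  expect_equal(M["ul", "dead"], m, tolerance = 1e-12)
  expect_equal(M["ul", "ur"], 0.19224 * (1 - 0.02688), tolerance = 1e-12)
})

test_that("zeroed cause-specific probabilities leave only scheduled moves", {
  M <- build_transition_matrix(quiet_params(), 2, zero_lt, base_cfg)
  # alive states persist; tunnels still advance deterministically
  expect_equal(M["ub_ng", "ub_ng"], 1)
  expect_equal(M["ul", "ul"], 1)
  expect_equal(M["dl_m1", "dl_m2"], 1)
  expect_equal(M["dl_m60", "df"], 1)
  expect_equal(M["dd_m48", "dd_late"], 1)
  expect_equal(M["dead", "dead"], 1)
})

test_that("an all-dead cohort stays dead and accrues nothing", {
  trace <- run_cohort(c(dead = 1), base_params, base_cfg, base_lt)
  expect_true(all(trace$occupancy[, "dead"] == 1))
  out <- accumulate_outcomes(trace, base_params, base_cfg)
  expect_equal(out$cost, 0)
  expect_equal(out$qaly, 0)
})

test_that("diagnosed-distant survival follows the year-band geometric form", {
  # first-year band 0.1255/month, background mortality off
  trace <- run_cohort(c(dd_m1 = 1), base_params, base_cfg, zero_lt)
  alive <- unname(1 - trace$occupancy[, "dead"])
  expect_equal(alive[13], (1 - 0.1255)^12, tolerance = 1e-10)
  expect_equal(alive[13], 0.200, tolerance = 1e-3)
  # subsequent bands switch at 12-month boundaries
  expect_equal(alive[25], (1 - 0.1255)^12 * (1 - 0.0670)^12, tolerance = 1e-10)
  # beyond month 48 the last band continues
  expect_equal(alive[61] / alive[49], (1 - 0.0150)^12, tolerance = 1e-10)
})

test_that("probability mass is conserved at every cycle of both strategies", {
  for (strategy in c("surveillance", "aabt")) {
    res <- evaluate_strategy(base_params, strategy, base_cfg, base_lt,
                             keep_trace = TRUE)
    sums <- rowSums(res$trace$occupancy)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(res$trace$occupancy >= -1e-15))
    expect_true(all(diff(res$trace$occupancy[, "dead"]) > -1e-12))
  }
})

test_that("discount factors follow (1 + r)^(-t/12)", {
  expect_equal(discount_factor(0, 0.035), 1)
  expect_equal(discount_factor(12, 0.035), 1 / 1.035)
  expect_equal(discount_factor(12, 0.035), 0.966184, tolerance = 1e-6)
  expect_equal(discount_factor(24, 0.035), discount_factor(12, 0.035)^2)
  expect_error(discount_factor(-1, 0.035), "non-negative")
})

test_that("QALY accumulation matches closed forms", {
  # no mortality, utility 1, no discounting: QALYs equal the horizon length
  params <- unit_utility_params(quiet_params())
  cfg <- unit_utility_config()
  trace <- run_cohort(c(ub_ng = 1), params, cfg, zero_lt)
  out <- accumulate_outcomes(trace, params, cfg)
  horizon_years <- (cfg$max_age - cfg$start_age)
  expect_equal(out$qaly, horizon_years, tolerance = 1e-9)

  # constant monthly survival p with discounting: geometric closed form with
  # half-weights on the first and last terms
  cfg2 <- base_cfg
  params2 <- unit_utility_params(quiet_params())
  flat_lt <- tibble::tibble(age = 0:100, qx = 1 - (1 - 0.01)^12)
  trace2 <- run_cohort(c(ub_ng = 1), params2, cfg2, flat_lt)
  out2 <- accumulate_outcomes(trace2, params2, cfg2)
  nt <- nodulecea:::n_cycles(cfg2)
  t_grid <- 0:nt
  w <- rep(1, nt + 1); w[c(1, nt + 1)] <- 0.5
  closed <- sum(w * (0.99^t_grid) * (1.035^(-t_grid / 12))) / 12
  expect_equal(out2$qaly, closed, tolerance = 1e-9)

  # half-cycle-corrected total lies between start- and end-of-cycle sums
  occ_u <- 0.99^t_grid * 1.035^(-t_grid / 12) / 12
  start_conv <- sum(occ_u[-length(occ_u)])
  end_conv <- sum(occ_u[-1])
  expect_gt(out2$qaly, min(start_conv, end_conv))
  expect_lt(out2$qaly, max(start_conv, end_conv))
})

test_that("with disease off, engine life expectancy matches the life-table closed form", {
  params <- unit_utility_params(quiet_params())
  cfg <- unit_utility_config()
  trace <- run_cohort(c(ub_ng = 1), params, cfg, base_lt)
  out <- accumulate_outcomes(trace, params, cfg)
  expect_equal(out$qaly, life_expectancy(base_lt, cfg$start_age), tolerance = 1e-6)
})

test_that("raising any mortality probability never increases total QALYs", {
  base_q <- evaluate_strategy(base_params, "surveillance", base_cfg, base_lt)$qaly
  for (nm in c("mort_undiag_malig", "mort_distant_y1", "mort_local_y2",
               "mort_regional_y3", "mort_biopsy", "mort_surgery_malig")) {
    bumped <- base_params
    bumped[[nm]] <- min(1, bumped[[nm]] * 1.5 + 0.01)
    q <- evaluate_strategy(bumped, "surveillance", base_cfg, base_lt)$qaly
    expect_lte(q, base_q + 1e-12)
  }
})

test_that("the cohort trace agrees with a multinomial micro-simulation", {
  init <- c(ub_ng = 0.7, ul = 0.1, ur = 0.05, ud = 0.05, dl_m1 = 0.05,
            dd_m1 = 0.05)
  n_ind <- 50000
  micro <- simulate_cohort_multinomial(init, base_params, base_cfg, base_lt,
                                       n_individuals = n_ind, n_cycles = 240,
                                       seed = 21)
  trace <- run_cohort(init, base_params, base_cfg, base_lt)
  for (cyc in c(12, 60, 240)) {
    p <- trace$occupancy[cyc + 1, ]
    phat <- micro[cyc + 1, ]
    mc_se <- sqrt(pmax(p * (1 - p), 1e-12) / n_ind)
    expect_true(all(abs(phat - p) <= 3 * mc_se + 1e-4),
                info = paste("cycle", cyc))
  }
})

test_that("results are invariant to the ordering of the initial vector", {
  a <- run_cohort(c(ub_ng = 0.9, ul = 0.1), base_params, base_cfg, base_lt)
  b <- run_cohort(c(ul = 0.1, ub_ng = 0.9), base_params, base_cfg, base_lt)
  expect_equal(a$occupancy, b$occupancy)
})

test_that("degenerate inputs are rejected", {
  expect_error(run_cohort(c(ub_ng = 0.5), base_params, base_cfg, base_lt),
               "sum to 1")
  expect_error(run_cohort(c(nonsense = 1), base_params, base_cfg, base_lt),
               "unknown state")
  expect_error(run_cohort(unname(c(1)), base_params, base_cfg, base_lt),
               "named")
})
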