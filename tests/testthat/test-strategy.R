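test_that("expected surgery outcomes match spreadsheet-style arithmetic", {
  # independent arithmetic over the printed tariffs and proportions
  malignant_cost <- (1 - 0.084) * 7713.03 + 0.084 * 10177.74 +
    (5 / 35) * 3252 + (11 / 35) * 4155.15
  benign_cost <- 0.935 * 3091.08 + 0.065 * 6733.76
  m <- expected_surgery_outcome(TRUE, base_params)
  b <- expected_surgery_outcome(FALSE, base_params)
  expect_equal(m$expected_cost, malignant_cost, tolerance = 1e-6)
  expect_equal(m$expected_cost, 9690.54, tolerance = 1e-4)
  expect_equal(m$mortality, 0.042)
  expect_equal(b$expected_cost, benign_cost, tolerance = 1e-6)
  expect_equal(b$expected_cost, 3327.85, tolerance = 1e-4)
  expect_equal(b$mortality, 0.005)
  # zero complication probability leaves tariff plus adjuvant terms
  p0 <- base_params; p0$comp_surgery_malig <- 0
  m0 <- expected_surgery_outcome(TRUE, p0)
  expect_equal(m0$expected_cost,
               7713.03 + (5 / 35) * 3252 + (11 / 35) * 4155.15,
               tolerance = 1e-6)
})

test_that("the upfront AABT split follows the probability tree", {
  # perfect test: all malignant to surgery, all benign to surveillance
  perfect <- apply_initial_test_split(base_params,
                                      list(sensitivity = 1, specificity = 1),
                                      base_cfg)
  prev <- base_params$prevalence
  mb <- base_params$mort_biopsy
  ms <- base_params$mort_surgery_malig
  expect_equal(perfect$state[["ub_ng"]], 1 - prev, tolerance = 1e-12)
  expect_equal(perfect$state[["ul"]], 0)
  expect_equal(perfect$state[["dl_m1"]],
               prev * 0.875 * (1 - mb) * (1 - ms), tolerance = 1e-12)
  expect_equal(sum(perfect$state), 1, tolerance = 1e-12)

  # Scenario A biopsy fraction: prev*sens + (1-prev)*(1-spec)
  split <- apply_initial_test_split(base_params, aabt_accuracy("A"), base_cfg)
  pos <- prev * 0.41 + (1 - prev) * 0.07
  expect_equal(pos, 0.10230, tolerance = 1e-5)
  # positives all pass through MDT + needle biopsy; recover from the cost
  upfront_minus_surgery <- split$cost - base_cfg$test_price -
    prev * 0.41 * (1 - mb) * expected_surgery_outcome(TRUE, base_params)$expected_cost
  expect_equal(upfront_minus_surgery, pos * (111.99 + 948.92),
               tolerance = 1e-9)
})

test_that("a zero-prevalence cohort pays the test price plus false-positive work-up", {
  params <- base_params
  params$prevalence <- 0
  test <- aabt_accuracy("A")
  surv <- evaluate_strategy(params, "surveillance", base_cfg, base_lt)
  aabt <- evaluate_strategy(params, "aabt", base_cfg, base_lt, test = test)
  fp <- 1 - test$specificity
  mb <- params$mort_biopsy
  # upfront difference: price + FP MDT/biopsy costs; downstream differences
  # only through the few biopsy deaths, which also save scan costs
  expected_upfront <- base_cfg$test_price +
    fp * (params$cost_mdt + params$cost_needle_biopsy)
  expect_equal(aabt$cost - surv$cost, expected_upfront, tolerance = 1)
  expect_lt(aabt$qaly, surv$qaly)  # biopsy deaths and SAEs only harm here
})

test_that("scan events charge the CT tariff and route detections correctly", {
  # all event probabilities zero: the scan adds exactly the CT tariff
  params <- quiet_params()
  params$ct_spec <- 1  # no false positives
  v <- stats::setNames(numeric(nrow(model_states(base_cfg))),
                       model_states(base_cfg)$state)
  v[c("ub_ng", "ul")] <- c(0.9, 0.1)
  out <- surveillance_scan_event(v, params, base_cfg, detect_malignant = FALSE)
  expect_equal(out$cost, 85.56 * 1.0, tolerance = 1e-12)
  expect_equal(out$qaly_adj, 0)
  expect_equal(out$state, v)

  # perfect CT sensitivity clears all undiagnosed malignant mass
  params2 <- base_params
  params2$ct_sens <- 1
  v2 <- v
  out2 <- surveillance_scan_event(v2, params2, base_cfg)
  expect_equal(out2$state[["ul"]], 0)
  expect_gt(out2$state[["dl_m1"]], 0)
  expect_equal(sum(out2$state), sum(v2), tolerance = 1e-12)
})

test_that("expected month-3 biopsies agree between trace propagation and a direct tree", {
  # Scenario-A-negative subcohort entering surveillance
  test <- aabt_accuracy("A")
  prev <- base_params$prevalence
  neg <- c(ub_ng = (1 - prev) * test$specificity,
           ul = prev * 0.875 * (1 - test$sensitivity),
           ur = prev * 0.125 * (1 - test$sensitivity))
  neg <- neg / sum(neg)

  # route 1: engine propagation to month 3, then the scan event
  trace <- run_cohort(neg, base_params, base_cfg, zero_lt)
  v3 <- trace$occupancy[4, ]
  out <- surveillance_scan_event(v3, base_params, base_cfg)
  # needle biopsies = FP on non-grown benign + detected malignant
  needle_trace <- v3[["ub_ng"]] * (1 - base_params$ct_spec) +
    (v3[["ul"]] + v3[["ur"]] + v3[["ud"]]) * base_params$ct_sens

  # route 2: direct probability tree over 3 cycles (background off)
  g1 <- base_params$growth_first_month; g2 <- base_params$growth_subsequent
  p <- base_params$prob_progression; m <- base_params$mort_undiag_malig
  not_grown <- neg[["ub_ng"]] * (1 - g1) * (1 - g2)^2
  # malignant stage occupancy after 3 progression/death cycles
  st <- c(l = neg[["ul"]], r = neg[["ur"]], d = 0)
  for (i in 1:3) {
    st <- c(l = st[["l"]] * (1 - p),
            r = (st[["l"]] * p + st[["r"]] * (1 - p)),
            d = (st[["r"]] * p + st[["d"]])) * (1 - m)
  }
  needle_tree <- not_grown * (1 - base_params$ct_spec) +
    sum(st) * base_params$ct_sens
  expect_equal(needle_trace, needle_tree, tolerance = 1e-10)
})

test_that("lifetime evaluation matches a disease-free closed form", {
  # zero prevalence and growth, full health: surveillance pays exactly three
  # discounted CT scans; QALYs equal discounted life expectancy
  params <- unit_utility_params(quiet_params())
  params$ct_spec <- 1  # no false-positive work-up
  res <- evaluate_strategy(params, "surveillance", base_cfg, base_lt)
  qm <- 1 - (1 - base_lt$qx[base_lt$age >= base_cfg$start_age])^(1 / 12)
  qm <- rep(qm, each = 12)[1:456]
  surv_curve <- c(1, cumprod(1 - qm))
  scans <- sum(85.56 * surv_curve[c(4, 13, 25)] *
                 discount_factor(c(3, 12, 24), 0.035))
  expect_equal(res$cost, scans, tolerance = 1e-9)
  w <- rep(1, 457); w[c(1, 457)] <- 0.5
  disc_ly <- sum(w * surv_curve * discount_factor(0:456, 0.035)) / 12
  expect_equal(res$qaly, disc_ly, tolerance = 1e-9)
})

test_that("total cost is exactly linear in the test price with slope one", {
  cfg0 <- base_cfg; cfg0$test_price <- 0
  cfg70 <- base_cfg; cfg70$test_price <- 70
  a0 <- evaluate_strategy(base_params, "aabt", cfg0, base_lt)
  a70 <- evaluate_strategy(base_params, "aabt", cfg70, base_lt)
  expect_equal(a70$cost - a0$cost, 70, tolerance = 1e-9)
  expect_equal(a70$qaly, a0$qaly, tolerance = 1e-12)
  # surveillance is unaffected by the test price
  s0 <- evaluate_strategy(base_params, "surveillance", cfg0, base_lt)
  s70 <- evaluate_strategy(base_params, "surveillance", cfg70, base_lt)
  expect_equal(s0$cost, s70$cost)
})

test_that("testing adds QALYs at base-case parameters", {
  tab <- evaluate_strategies(base_params, c("surveillance", "aabt_A", "aabt_B"),
                             base_cfg, base_lt)
  q <- stats::setNames(tab$qaly, tab$strategy)
  expect_gt(q[["aabt_A"]], q[["surveillance"]])
  expect_gt(q[["aabt_B"]], q[["surveillance"]])
  # unit costs move total cost monotonically
  bumped <- base_params; bumped$cost_ct <- bumped$cost_ct * 2
  s_b <- evaluate_strategy(bumped, "surveillance", base_cfg, base_lt)
  s <- evaluate_strategy(base_params, "surveillance", base_cfg, base_lt)
  expect_gt(s_b$cost, s$cost)
})
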