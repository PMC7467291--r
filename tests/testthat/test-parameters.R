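test_that("se_from_range evaluates the 95%-range formula and its properties", {
  expect_equal(se_from_range(0.165, 0.078), (0.165 - 0.078) / 3.92)
  expect_equal(se_from_range(0.165, 0.078), 0.02219, tolerance = 1e-3)
  expect_equal(se_from_range(0.11, 0.048), 0.01582, tolerance = 1e-3)
  expect_equal(se_from_range(0.3, 0.3), 0)
  # translation invariance
  for (c_shift in c(-0.05, 0.1, 2)) {
    expect_equal(se_from_range(0.165 + c_shift, 0.078 + c_shift),
                 se_from_range(0.165, 0.078))
  }
  expect_error(se_from_range(0.1, 0.2), "upper")
})

test_that("beta_from_moments recovers the requested moments", {
  mom <- beta_from_moments(0.125, 0.02219)
  expect_equal(mom$alpha, 27.6, tolerance = 0.01)
  expect_equal(mom$beta, 193.5, tolerance = 0.01)
  # fitted Beta must have the given mean and se (closed-form moments)
  cases <- list(c(0.125, 0.02219), c(0.5, 0.1), c(0.9, 0.02), c(0.005, 0.00255))
  for (cs in cases) {
    mm <- beta_from_moments(cs[1], cs[2])
    fit_mean <- mm$alpha / (mm$alpha + mm$beta)
    fit_var <- mm$alpha * mm$beta /
      ((mm$alpha + mm$beta)^2 * (mm$alpha + mm$beta + 1))
    expect_equal(fit_mean, cs[1], tolerance = 1e-12)
    expect_equal(sqrt(fit_var), cs[2], tolerance = 1e-10)
  }
  expect_error(beta_from_moments(0.5, 0.6), "infeasible")
  expect_error(beta_from_moments(0, 0.1), "fixed")
  expect_error(beta_from_moments(1, 0.1), "fixed")
})

test_that("the bundled registry reproduces the published base-case inputs", {
  defs <- base_defs
  get_base <- function(nm) defs$base[defs$name == nm]
  expect_equal(get_base("cost_needle_biopsy"), 948.92)
  expect_equal(get_base("prevalence"), 0.095)
  expect_match(defs$source[defs$name == "prevalence"], "7/74")
  expect_equal(get_base("prob_progression"), 0.19224)
  expect_equal(get_base("mort_undiag_malig"), 0.02688)
  expect_equal(get_base("u_age_55_64"), 0.810)
  expect_equal(get_base("cost_ct"), 85.56)
})

test_that("parameter table validation names the offending rows", {
  defs <- base_defs
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- defs
  bad$base[bad$name == "u_local"] <- 1.2
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_parameter_table(path), "u_local")

  bad <- defs
  bad$base[bad$name == "cost_ct"] <- -5
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_parameter_table(path), "cost_ct")

  bad <- defs
  bad$extra_column <- 1
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(load_parameter_table(path), "unknown field")
})

test_that("registry serialization round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(base_defs, path, row.names = FALSE, na = "")
  reloaded <- load_parameter_table(path)
  expect_equal(as.data.frame(reloaded), as.data.frame(base_defs))
})

test_that("deterministic draws return base values and seeds make sampling reproducible", {
  ps <- draw_parameter_set(base_defs, probabilistic = FALSE)
  for (nm in base_defs$name) {
    expect_equal(ps[[nm]], base_defs$base[base_defs$name == nm],
                 info = nm, tolerance = 1e-12)
  }
  a <- draw_parameter_set(base_defs, seed = 42, probabilistic = TRUE)
  b <- draw_parameter_set(base_defs, seed = 42, probabilistic = TRUE)
  expect_identical(unclass(a), unclass(b))
  c_ <- draw_parameter_set(base_defs, seed = 43, probabilistic = TRUE)
  expect_false(identical(unclass(a), unclass(c_)))
})

test_that("sampled probabilities stay in [0, 1] and match their target moments", {
  draws <- draw_parameter_sets(base_defs, 10000, seed = 11)
  bounded <- base_defs$name[base_defs$units %in%
    c("probability/month", "probability/event", "proportion", "utility")]
  for (nm in bounded) {
    expect_true(all(draws[[nm]] >= 0 & draws[[nm]] <= 1), info = nm)
  }
  # regional-stage proportion: mean within 3 MC-SE of 0.125
  x <- draws$stage_regional
  mc_se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.125), 3 * mc_se + 1e-4)
  # stage shares stay complementary in every draw
  expect_equal(draws$stage_local + draws$stage_regional,
               rep(1, nrow(draws)), tolerance = 1e-12)
  # CT accuracy is drawn jointly: sensitivity is the HSROC image of the
  # sampled specificity and lambda in every draw
  expect_equal(draws$ct_sens,
               hsroc_sensitivity(draws$ct_spec, draws$hsroc_lambda,
                                 draws$hsroc_beta),
               tolerance = 1e-12)
})
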