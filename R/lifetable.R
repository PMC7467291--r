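#' Generate a Gompertz life table
#'
#' Produces an age-indexed table of annual death probabilities
#' `qx = 1 - exp(-a * exp(b * age))`, the discrete analogue of a Gompertz
#' mortality hazard. The defaults are calibrated so that remaining life
#' expectancy at age 62 is approximately 23 years, matching UK-like all-cause
#' mortality; they emulate a national statistics life table when the real one
#' is not supplied (see [load_life_table()]).
#'
#' @param a Baseline annual hazard at age 0; positive.
#' @param b Log-slope of the hazard per year of age; non-negative.
#' @param max_age Last age in the table; `qx` is set to 1 there so the table
#'   closes out.
#' @return A tibble with columns `age` (0..`max_age`) and `qx`, carrying a
#'   `source` attribute.
#' @examples
#' lt <- gompertz_life_table()
#' life_expectancy(lt, from_age = 62)
#' @export
gompertz_life_table <- function(a = 1.483013e-05, b = 0.10, max_age = 100) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive", call. = FALSE)
  if (!is.numeric(b) || b < 0) stop("`b` must be non-negative", call. = FALSE)
  age <- 0:max_age
  qx <- -expm1(-a * exp(b * age))
  qx[length(qx)] <- 1
  lt <- tibble::tibble(age = age, qx = qx)
  attr(lt, "source") <- sprintf("synthetic Gompertz life table (a=%.4g, b=%.3g)", a, b)
  lt
}

#' Load a life table from CSV
#'
#' Reads a two-column CSV (`age`, `qx`) of annual death probabilities, e.g. a
#' national statistics life table. Missing intermediate ages are filled by
#' linear interpolation (with a warning); ages missing above the top of the
#' table are extended by Gompertz extrapolation fitted to the oldest 15
#' observed ages (with a warning).
#'
#' @param path CSV file with columns `age` and `qx`.
#' @param max_age Age up to which the table is required.
#' @return A tibble with columns `age` (0..`max_age`) and `qx`.
#' @export
load_life_table <- function(path, max_age = 100) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(raw))) {
    stop("life table must have columns `age` and `qx`", call. = FALSE)
  }
  raw <- raw[order(raw$age), ]
  if (any(raw$qx < 0 | raw$qx > 1)) {
    stop("life table qx values must lie in [0, 1]", call. = FALSE)
  }
  ages <- 0:max_age
  qx <- rep(NA_real_, length(ages))
  qx[match(raw$age, ages)] <- raw$qx
  inner <- seq(min(raw$age), min(max(raw$age), max_age))
  if (anyNA(qx[inner + 1])) {
    warning("life table has gaps; filling by linear interpolation")
    qx[inner + 1] <- stats::approx(raw$age, raw$qx, xout = inner)$y
  }
  if (min(raw$age) > 0) qx[seq_len(min(raw$age))] <- raw$qx[1]
  if (max(raw$age) < max_age) {
    warning("life table ends at age ", max(raw$age),
            "; extending to ", max_age, " by Gompertz extrapolation")
    top <- raw[raw$age >= max(raw$age) - 14 & raw$qx > 0 & raw$qx < 1, ]
    hz <- -log1p(-top$qx)
    fit <- stats::lm(log(hz) ~ top$age)
    miss <- ages[ages > max(raw$age)]
    qx[miss + 1] <- -expm1(-exp(fit$coefficients[1] + fit$coefficients[2] * miss))
  }
  qx[length(qx)] <- 1
  qx <- pmin(pmax(qx, 0), 1)
  lt <- tibble::tibble(age = ages, qx = qx)
  attr(lt, "source") <- path
  lt
}

# monthly death probability at each integer age of a life table
monthly_qx <- function(life_table, ages) {
  idx <- match(pmin(ages, max(life_table$age)), life_table$age)
  1 - (1 - life_table$qx[idx])^(1 / 12)
}

#' Remaining life expectancy from a life table
#'
#' Closed-form (non-Markov) computation of remaining life expectancy at a
#' given age, on a monthly grid with half-weights on the first and last time
#' points — the same accumulation convention as the cohort engine, so the two
#' routes are directly comparable.
#'
#' @param life_table A life table tibble (`age`, `qx`).
#' @param from_age Starting age in years.
#' @param max_age Truncation age.
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(life_table, from_age = 62, max_age = max(life_table$age)) {
  n_cycles <- (max_age - from_age) * 12
  age_at_cycle <- from_age + ((seq_len(n_cycles) - 1) %/% 12)
  qm <- monthly_qx(life_table, age_at_cycle)
  surv <- c(1, cumprod(1 - qm))
  w <- rep(1, length(surv))
  w[c(1, length(w))] <- 0.5
  sum(w * surv) / 12
}
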