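#' Convert a printed uncertainty range to a standard error
#'
#' Ranges reported as `(lower-upper)` around a point estimate are converted to
#' a standard error assuming the range spans approximately 95% of a symmetric
#' sampling distribution: `SE = (upper - lower) / (2 * 1.96)`.
#'
#' @param upper,lower Numeric vectors; the upper and lower limits of the range.
#'   `upper` must be greater than or equal to `lower` elementwise.
#' @return Numeric vector of standard errors.
#' @examples
#' se_from_range(0.165, 0.078)
#' @export
se_from_range <- function(upper, lower) {
  if (!is.numeric(upper) || !is.numeric(lower)) {
    stop("`upper` and `lower` must be numeric", call. = FALSE)
  }
  if (any(upper < lower, na.rm = TRUE)) {
    stop("`upper` must be >= `lower`", call. = FALSE)
  }
  (upper - lower) / (2 * 1.96)
}

#' Fit a Beta distribution by the method of moments
#'
#' Returns the `(alpha, beta)` shape parameters of the Beta distribution with
#' the given mean and standard error: `alpha = mean * k`,
#' `beta = (1 - mean) * k` with `k = mean * (1 - mean) / se^2 - 1`.
#'
#' @param mean Mean of the distribution, strictly inside (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#' @return A named list with elements `alpha` and `beta`.
#' @examples
#' beta_from_moments(0.125, 0.0222)
#' @export
beta_from_moments <- function(mean, se) {
  stopifnot_scalar(mean)
  stopifnot_scalar(se)
  if (mean <= 0 || mean >= 1) {
    stop("`mean` must be strictly inside (0, 1); use a fixed parameter for ",
         "degenerate values", call. = FALSE)
  }
  if (se <= 0) stop("`se` must be positive", call. = FALSE)
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop("infeasible moments: se^2 = ", signif(v, 4), " >= mean*(1-mean) = ",
         signif(mean * (1 - mean), 4), call. = FALSE)
  }
  k <- mean * (1 - mean) / v - 1
  list(alpha = mean * k, beta = (1 - mean) * k)
}

param_units <- c("probability/month", "probability/event", "GBP", "utility",
                 "proportion", "logit")
param_families <- c("fixed", "beta", "normal", "derived")
param_columns <- c("name", "base", "family", "se", "low", "high", "events",
                   "denom", "range_type", "units", "source")

#' Load and validate a model parameter registry
#'
#' Reads a column-typed CSV describing every model input: its base value,
#' uncertainty family (`fixed`, `beta`, `normal`, `derived`), standard error
#' or range or event counts, units and source. The bundled registry
#' (see [ipn_parameters()]) reproduces the published base-case inputs of the
#' lung-nodule testing model.
#'
#' @param path Path to a CSV file with columns
#'   `name, base, family, se, low, high, events, denom, range_type, units, source`.
#' @return A tibble with one row per parameter definition.
#' @seealso [ipn_parameters()], [draw_parameter_set()]
#' @export
load_parameter_table <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), param_columns)
  if (length(extra) > 0) {
    stop("unknown field(s) in parameter table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(param_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("parameter table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  defs <- tibble::as_tibble(raw)
  for (col in c("base", "se", "low", "high", "events", "denom")) {
    defs[[col]] <- suppressWarnings(as.numeric(defs[[col]]))
  }
  validate_parameter_defs(defs)
  defs
}

validate_parameter_defs <- function(defs) {
  bad_family <- !defs$family %in% param_families
  if (any(bad_family)) {
    stop("invalid family for parameter(s): ",
         paste(defs$name[bad_family], collapse = ", "), call. = FALSE)
  }
  bad_units <- !defs$units %in% param_units
  if (any(bad_units)) {
    stop("invalid units for parameter(s): ",
         paste(defs$name[bad_units], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(defs$name)) {
    stop("duplicated parameter name(s): ",
         paste(unique(defs$name[duplicated(defs$name)]), collapse = ", "),
         call. = FALSE)
  }
  bounded <- defs$units %in% c("probability/month", "probability/event",
                               "utility", "proportion")
  bad_prob <- bounded & (defs$base < 0 | defs$base > 1)
  if (any(bad_prob)) {
    stop("probability/utility/proportion outside [0, 1] for parameter(s): ",
         paste(defs$name[bad_prob], collapse = ", "), call. = FALSE)
  }
  costs <- defs$units == "GBP"
  if (any(costs & defs$base < 0)) {
    stop("negative cost for parameter(s): ",
         paste(defs$name[costs & defs$base < 0], collapse = ", "), call. = FALSE)
  }
  has_range <- !is.na(defs$low) & !is.na(defs$high)
  bad_range <- has_range & !(defs$low <= defs$base & defs$base <= defs$high)
  if (any(bad_range)) {
    stop("base value outside its (low, high) range for parameter(s): ",
         paste(defs$name[bad_range], collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(defs$se) & defs$se < 0)) {
    stop("negative se for parameter(s): ",
         paste(defs$name[!is.na(defs$se) & defs$se < 0], collapse = ", "),
         call. = FALSE)
  }
  invisible(defs)
}

#' The bundled model parameter registry
#'
#' Every published base-case input of the model: test accuracy, transition
#' probabilities, unit costs (GBP, 2016/17 price year) and utilities, together
#' with the uncertainty specification used in probabilistic sensitivity
#' analysis.
#'
#' @return A tibble of parameter definitions (see [load_parameter_table()]).
#' @export
ipn_parameters <- function() {
  load_parameter_table(
    system.file("extdata", "parameters.csv", package = "nodulecea",
                mustWork = TRUE)
  )
}

# Resolve each uncertain parameter to an explicit sampling rule.
# pm50 ranges denote +/-50% multiplicative bounds; by default on the
# probability itself, optionally on the underlying exponential rate.
resolve_distributions <- function(defs, pm50_on_rate = FALSE) {
  purrr::pmap(defs, function(name, base, family, se, low, high, events, denom,
                             range_type, units, source) {
    if (family %in% c("fixed", "derived")) {
      return(list(name = name, family = family, base = base))
    }
    if (family == "normal") {
      if (is.na(se)) stop("normal parameter `", name, "` needs an se", call. = FALSE)
      return(list(name = name, family = "normal", base = base, mean = base, sd = se))
    }
    # beta
    if (identical(range_type, "counts")) {
      if (is.na(events) || is.na(denom) || events <= 0 || denom <= events) {
        stop("count parameter `", name, "` needs 0 < events < denom", call. = FALSE)
      }
      return(list(name = name, family = "beta", base = base,
                  alpha = events, beta = denom - events))
    }
    if (is.na(se)) {
      if (identical(range_type, "pm50")) {
        if (pm50_on_rate) {
          r <- -log1p(-base)
          low <- -expm1(-0.5 * r)
          high <- -expm1(-1.5 * r)
        } else {
          low <- 0.5 * base
          high <- 1.5 * base
        }
      }
      if (is.na(low) || is.na(high)) {
        stop("beta parameter `", name, "` needs an se, a range, or counts",
             call. = FALSE)
      }
      se <- se_from_range(high, low)
    }
    mom <- beta_from_moments(base, se)
    list(name = name, family = "beta", base = base,
         alpha = mom$alpha, beta = mom$beta)
  })
}

#' Draw one complete parameter set
#'
#' Realizes every parameter in the registry, either at its base value
#' (`probabilistic = FALSE`) or by sampling from its uncertainty distribution:
#' Beta for probabilities, proportions and utilities (method of moments, or
#' the conjugate `Beta(events, n - events)` form where event counts are
#' published), Normal for the HSROC accuracy parameter. CT sensitivity and
#' specificity are always drawn jointly through the HSROC curve
#' (see [sample_ct_accuracy()]), never independently.
#'
#' @param defs Parameter registry tibble, e.g. [ipn_parameters()].
#' @param seed Optional integer seed (applied before sampling).
#' @param probabilistic If `FALSE`, return base values.
#' @param pm50_on_rate Interpret +/-50% ranges as bounds on the underlying
#'   exponential rate rather than on the monthly probability.
#' @param draw_id Integer label stored on the result (0 = base case).
#' @return A named list of realized values with class `"ipn_params"`.
#' @export
draw_parameter_set <- function(defs, seed = NULL, probabilistic = FALSE,
                               pm50_on_rate = FALSE, draw_id = if (probabilistic) 1L else 0L) {
  dists <- resolve_distributions(defs, pm50_on_rate = pm50_on_rate)
  names(dists) <- defs$name
  if (!is.null(seed)) set.seed(seed)
  values <- vapply(dists, function(d) {
    if (!probabilistic || d$family %in% c("fixed", "derived")) return(d$base)
    switch(d$family,
      beta = stats::rbeta(1, d$alpha, d$beta),
      normal = stats::rnorm(1, d$mean, d$sd),
      stop("unhandled family: ", d$family)
    )
  }, numeric(1))
  params <- as.list(values)
  # joint/derived quantities
  params$stage_local <- 1 - params$stage_regional
  if (probabilistic) {
    params$ct_sens <- hsroc_sensitivity(params$ct_spec, params$hsroc_lambda,
                                        params$hsroc_beta)
  }
  structure(params, class = "ipn_params",
            draw_id = draw_id, seed = seed, probabilistic = probabilistic)
}

#' Draw many parameter sets for probabilistic analysis
#'
#' @inheritParams draw_parameter_set
#' @param n_draws Number of parameter sets.
#' @param seed Integer seed controlling the whole sequence.
#' @return A tibble with a `draw` column and one column per parameter.
#' @export
draw_parameter_sets <- function(defs, n_draws, seed = 1L,
                                probabilistic = TRUE, pm50_on_rate = FALSE) {
  stopifnot(n_draws >= 1)
  set.seed(seed)
  draws <- purrr::map(seq_len(n_draws), function(i) {
    ps <- draw_parameter_set(defs, seed = NULL, probabilistic = probabilistic,
                             pm50_on_rate = pm50_on_rate, draw_id = i)
    tibble::as_tibble(unclass(ps))
  })
  dplyr::bind_rows(draws) |>
    dplyr::mutate(draw = dplyr::row_number(), .before = 1)
}

#' @export
print.ipn_params <- function(x, ...) {
  cat("<ipn_params> draw", attr(x, "draw_id"),
      if (isTRUE(attr(x, "probabilistic"))) "(probabilistic)" else "(base case)",
      "-", length(x), "parameters\n")
  invisible(x)
}
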