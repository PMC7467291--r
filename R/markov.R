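# The monthly-cycle Markov cohort engine.
#
# State space (tunnel sub-states expand the diagnosed cancer states so that
# year-banded excess mortality and the 5-year disease-free exit are exact):
#   ub_ng / ub_g   undiagnosed benign nodule, growth flag not fired / fired
#   ul, ur, ud     undiagnosed malignant: local, regional, distant
#   db             diagnosed benign (post surgical biopsy)
#   dl_m1..m60     diagnosed local, months since diagnosis (exit -> df)
#   dr_m1..m60     diagnosed regional, months since diagnosis (exit -> df)
#   dd_m1..m48     diagnosed distant, months since diagnosis
#   dd_late        diagnosed distant beyond 48 months (constant excess risk)
#   df             disease free
#   dead           absorbing

#' State table of the cohort model
#'
#' @param config A [scenario_config()] object.
#' @return A tibble with columns `state`, `group` and `tunnel` (months since
#'   diagnosis for tunnel sub-states).
#' @export
model_states <- function(config = scenario_config()) {
  tm <- config$tunnel_months
  dm <- config$distant_tunnel_months
  key <- paste(tm, dm)
  cached <- .state_cache[[key]]
  if (!is.null(cached)) return(cached)
  .state_cache[[key]] <- build_state_table(tm, dm)
  .state_cache[[key]]
}

.state_cache <- new.env(parent = emptyenv())

build_state_table <- function(tm, dm) {
  tibble::tibble(
    state = c("ub_ng", "ub_g", "ul", "ur", "ud", "db",
              paste0("dl_m", seq_len(tm)), paste0("dr_m", seq_len(tm)),
              paste0("dd_m", seq_len(dm)), "dd_late", "df", "dead"),
    group = c("benign_undiag", "benign_undiag", "undiag_local",
              "undiag_regional", "undiag_distant", "diag_benign",
              rep("diag_local", tm), rep("diag_regional", tm),
              rep("diag_distant", dm), "diag_distant", "disease_free", "dead"),
    tunnel = c(rep(NA_integer_, 6), seq_len(tm), seq_len(tm), seq_len(dm),
               NA_integer_, NA_integer_, NA_integer_)
  )
}

# year band (1..4) for a tunnel month, capping at the last printed band
tunnel_year <- function(month) pmin((month - 1) %/% 12 + 1, 4)

#' Build the transition matrix for one model cycle
#'
#' Assembles the row-stochastic monthly transition matrix for a given cycle.
#' Within a cycle, events compose in the order: disease progression, then
#' cause-specific (excess) mortality, then age-specific background mortality,
#' so e.g. the probability of moving from undiagnosed local to undiagnosed
#' regional is `p_progress * (1 - excess) * (1 - background)`.
#'
#' @param params An `ipn_params` parameter set.
#' @param cycle Cycle index (1-based); governs the benign growth probability
#'   (first month vs subsequent) and the cohort's attained age.
#' @param life_table A life table tibble (`age`, `qx`).
#' @param config A [scenario_config()].
#' @return A named square matrix over [model_states()], rows summing to 1.
#' @export
build_transition_matrix <- function(params, cycle, life_table,
                                    config = scenario_config()) {
  stopifnot(cycle >= 1)
  states <- model_states(config)
  S <- nrow(states)
  nm <- states$state
  M <- matrix(0, S, S, dimnames = list(nm, nm))
  i <- function(s) match(s, nm)

  age <- config$start_age + (cycle - 1) %/% 12
  bg <- monthly_qx(life_table, age)
  g <- if (cycle == 1) pval(params, "growth_first_month") else pval(params, "growth_subsequent")
  p <- pval(params, "prob_progression")
  m_und <- pval(params, "mort_undiag_malig")
  loc <- vapply(1:4, function(y) pval(params, paste0("mort_local_y", y)), numeric(1))
  reg <- vapply(1:4, function(y) pval(params, paste0("mort_regional_y", y)), numeric(1))
  dis <- vapply(1:4, function(y) pval(params, paste0("mort_distant_y", y)), numeric(1))

  dead <- i("dead")
  # benign, disease-free, diagnosed-benign: background mortality only
  M[i("ub_ng"), i("ub_g")] <- g * (1 - bg)
  M[i("ub_ng"), i("ub_ng")] <- (1 - g) * (1 - bg)
  M[i("ub_ng"), dead] <- bg
  M[i("ub_g"), i("ub_g")] <- 1 - bg
  M[i("ub_g"), dead] <- bg
  M[i("db"), i("db")] <- 1 - bg
  M[i("db"), dead] <- bg
  M[i("df"), i("df")] <- 1 - bg
  M[i("df"), dead] <- bg

  # undiagnosed malignant: progression, excess mortality, background
  alive_u <- (1 - m_und) * (1 - bg)
  M[i("ul"), i("ur")] <- p * alive_u
  M[i("ul"), i("ul")] <- (1 - p) * alive_u
  M[i("ul"), dead] <- 1 - alive_u
  M[i("ur"), i("ud")] <- p * alive_u
  M[i("ur"), i("ur")] <- (1 - p) * alive_u
  M[i("ur"), dead] <- 1 - alive_u
  M[i("ud"), i("ud")] <- alive_u
  M[i("ud"), dead] <- 1 - alive_u

  # diagnosed tunnels: excess mortality by year since diagnosis + background
  tm <- config$tunnel_months
  dm <- config$distant_tunnel_months
  fill_tunnel <- function(prefix, rates, n, final_state) {
    from <- i(paste0(prefix, "_m", seq_len(n)))
    to <- c(i(paste0(prefix, "_m", seq_len(n - 1) + 1)), i(final_state))
    surv <- (1 - rates[tunnel_year(seq_len(n))]) * (1 - bg)
    M[cbind(from, to)] <<- surv
    M[cbind(from, dead)] <<- 1 - surv
  }
  fill_tunnel("dl", loc, tm, "df")
  fill_tunnel("dr", reg, tm, "df")
  fill_tunnel("dd", dis, dm, "dd_late")
  surv_late <- (1 - dis[4]) * (1 - bg)
  M[i("dd_late"), i("dd_late")] <- surv_late
  M[i("dd_late"), dead] <- 1 - surv_late

  M[dead, dead] <- 1

  rs <- rowSums(M)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("internal error: transition matrix rows off unity by up to ",
         max(abs(rs - 1)), call. = FALSE)
  }
  M
}

# Build the distinct matrices needed for a full run (one per attained age
# year, plus the first-cycle variant) and a cycle -> matrix index map.
# Because background mortality enters every row as an independent competing
# risk, each age's matrix is an affine rescaling of the cause-specific
# (background-free) matrix: M = C * (1 - bg), then bg added to the dead
# column. Only the two cause-specific matrices (first cycle vs subsequent)
# are assembled entry by entry.
transition_matrix_set <- function(params, life_table, config = scenario_config()) {
  nc <- n_cycles(config)
  zero_lt <- tibble::tibble(age = 0:config$max_age, qx = 0)
  c_first <- build_transition_matrix(params, 1L, zero_lt, config)
  c_later <- build_transition_matrix(params, 2L, zero_lt, config)
  dead <- match("dead", colnames(c_first))

  age_idx <- (seq_len(nc) - 1) %/% 12
  key <- ifelse(seq_len(nc) == 1L, "first", as.character(age_idx))
  ukeys <- unique(key)
  mats <- lapply(ukeys, function(k) {
    first <- k == "first"
    age <- config$start_age + if (first) 0L else as.integer(k)
    bg <- monthly_qx(life_table, age)
    M <- (if (first) c_first else c_later) * (1 - bg)
    M[, dead] <- M[, dead] + bg
    M
  })
  names(mats) <- ukeys
  list(mats = mats, idx = match(key, ukeys))
}

#' Run the Markov cohort
#'
#' Propagates an initial distribution over [model_states()] through the
#' cycle-specific transition matrices up to the lifetime horizon, applying
#' scheduled events (the upfront test split, surveillance scans) at their
#' cycle of occurrence.
#'
#' @param initial Named numeric vector over the model states, summing to 1
#'   (tolerance 1e-8). Missing names are taken as 0.
#' @param params An `ipn_params` parameter set.
#' @param config A [scenario_config()].
#' @param life_table A life table tibble.
#' @param events Named list of event functions; names are the times (months,
#'   `"0"` = before the first cycle) at which each fires. An event function
#'   receives `(state_vector, params, config)` and returns
#'   `list(state =, cost =, qaly_adj =)`.
#' @param matrices Optional precomputed result of an internal matrix-set
#'   build, reused across strategies sharing one parameter set.
#' @return An object of class `"ipn_trace"`: occupancy matrix
#'   (times 0..T by states), event ledger, config.
#' @export
run_cohort <- function(initial, params, config = scenario_config(),
                       life_table = gompertz_life_table(max_age = config$max_age),
                       events = list(), matrices = NULL) {
  states <- model_states(config)
  v <- stats::setNames(numeric(nrow(states)), states$state)
  if (is.null(names(initial))) {
    stop("`initial` must be a named vector over model states", call. = FALSE)
  }
  unknown <- setdiff(names(initial), states$state)
  if (length(unknown) > 0) {
    stop("unknown state(s) in `initial`: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  v[names(initial)] <- initial
  if (abs(sum(v) - 1) > 1e-8) {
    stop("`initial` must sum to 1 (got ", sum(v), ")", call. = FALSE)
  }
  if (is.null(matrices)) {
    matrices <- transition_matrix_set(params, life_table, config)
  }
  nc <- n_cycles(config)
  occ <- matrix(0, nc + 1, nrow(states), dimnames = list(0:nc, states$state))
  ev_time <- numeric(0); ev_cost <- numeric(0); ev_qaly <- numeric(0); ev_lab <- character(0)

  apply_event <- function(v, t) {
    f <- events[[as.character(t)]]
    if (is.null(f)) return(v)
    out <- f(v, params, config)
    if (abs(sum(out$state) - sum(v)) > 1e-9) {
      stop("event at month ", t, " did not conserve probability mass",
           call. = FALSE)
    }
    ev_time <<- c(ev_time, t)
    ev_cost <<- c(ev_cost, out$cost %||% 0)
    ev_qaly <<- c(ev_qaly, out$qaly_adj %||% 0)
    ev_lab <<- c(ev_lab, out$label %||% "event")
    out$state
  }

  v <- apply_event(v, 0)
  occ[1, ] <- v
  for (t in seq_len(nc)) {
    v <- as.numeric(v %*% matrices$mats[[matrices$idx[t]]])
    names(v) <- states$state
    v <- apply_event(v, t)
    occ[t + 1, ] <- v
  }
  structure(list(
    occupancy = occ,
    events = tibble::tibble(time = ev_time, label = ev_lab,
                            cost = ev_cost, qaly_adj = ev_qaly),
    config = config,
    states = states
  ), class = "ipn_trace")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discount factor for a model cycle
#'
#' @param cycle Time in months since model entry.
#' @param annual_rate Annual discount rate.
#' @return `(1 + annual_rate)^(-cycle / 12)`.
#' @export
discount_factor <- function(cycle, annual_rate = 0.035) {
  if (any(cycle < 0)) stop("`cycle` must be non-negative", call. = FALSE)
  (1 + annual_rate)^(-cycle / 12)
}

# utility of each state group at a given attained age, under the config's
# undiagnosed-state utility rule
state_utilities <- function(params, config, ages) {
  u_age <- ifelse(ages >= 75, pval(params, "u_age_75plus"),
           ifelse(ages >= 65, pval(params, "u_age_65_74"),
                  pval(params, "u_age_55_64")))
  cap <- function(u) pmin(u, u_age)
  list(
    benign_undiag = u_age,
    diag_benign = u_age,
    disease_free = u_age,
    undiag_local = if (config$undiag_cancer_utilities) cap(pval(params, "u_local")) else u_age,
    undiag_regional = if (config$undiag_cancer_utilities) cap(pval(params, "u_regional")) else u_age,
    undiag_distant = if (config$undiag_cancer_utilities) cap(pval(params, "u_distant")) else u_age,
    diag_local = cap(pval(params, "u_local")),
    diag_regional = cap(pval(params, "u_regional")),
    diag_distant = cap(pval(params, "u_distant")),
    dead = rep(0, length(ages))
  )
}

#' Accumulate lifetime discounted costs and QALYs from a cohort trace
#'
#' State occupancy earns utility (age-banded population norms for benign and
#' disease-free states, stage-specific cancer utilities capped by the age
#' norm otherwise) at `utility / 12` QALY per monthly cycle, discounted at
#' the configured annual rate with half-weights on the first and last time
#' points (half-cycle correction). Event-triggered costs and one-off QALY
#' decrements recorded on the trace are added at their cycle of occurrence.
#'
#' @param trace An `ipn_trace` from [run_cohort()].
#' @param params The parameter set the trace was generated under.
#' @param config A [scenario_config()].
#' @return A list with `cost`, `qaly` (discounted) and `cost_undisc`,
#'   `qaly_undisc`.
#' @export
accumulate_outcomes <- function(trace, params, config = trace$config) {
  occ <- trace$occupancy
  nt <- nrow(occ)
  times <- 0:(nt - 1)
  ages <- config$start_age + times %/% 12
  disc <- discount_factor(times, config$discount_annual)
  w <- rep(1, nt); w[c(1, nt)] <- 0.5

  u <- state_utilities(params, config, ages)
  # per-time utility-weighted occupancy
  uocc <- numeric(nt)
  for (grp in unique(trace$states$group)) {
    cols <- which(trace$states$group == grp)
    mass <- if (length(cols) == 1) occ[, cols] else rowSums(occ[, cols, drop = FALSE])
    uocc <- uocc + mass * u[[grp]]
  }
  qaly_cycles <- uocc / 12
  qaly <- sum(w * disc * qaly_cycles)
  qaly_undisc <- sum(w * qaly_cycles)

  ev <- trace$events
  ev_disc <- discount_factor(ev$time, config$discount_annual)
  cost <- sum(ev_disc * ev$cost)
  cost_undisc <- sum(ev$cost)
  qaly <- qaly + sum(ev_disc * ev$qaly_adj)
  qaly_undisc <- qaly_undisc + sum(ev$qaly_adj)

  list(cost = cost, qaly = qaly,
       cost_undisc = cost_undisc, qaly_undisc = qaly_undisc)
}

#' @export
print.ipn_trace <- function(x, ...) {
  cat("<ipn_trace>", nrow(x$occupancy) - 1, "cycles,",
      ncol(x$occupancy), "states,", nrow(x$events), "events\n")
  invisible(x)
}

#' Tidy a cohort trace
#'
#' @param x An `ipn_trace`.
#' @param ... Unused.
#' @return A long tibble with columns `time`, `age`, `group`, `state`,
#'   `occupancy`.
#' @method tidy ipn_trace
#' @export
tidy.ipn_trace <- function(x, ...) {
  occ <- x$occupancy
  tibble::tibble(
    time = rep(as.integer(rownames(occ)), times = ncol(occ)),
    state = rep(colnames(occ), each = nrow(occ)),
    occupancy = as.numeric(occ)
  ) |>
    dplyr::left_join(x$states, by = "state") |>
    dplyr::mutate(age = x$config$start_age + .data$time / 12) |>
    dplyr::select("time", "age", "group", "state", "occupancy")
}
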