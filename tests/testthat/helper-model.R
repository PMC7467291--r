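# shared fixtures, built in code

base_defs <- ipn_parameters()
base_params <- draw_parameter_set(base_defs)
base_lt <- gompertz_life_table()
base_cfg <- scenario_config("A")

# a zero-mortality life table for closed-form checks
zero_lt <- tibble::tibble(age = 0:100, qx = 0)

# parameter set with all disease processes switched off
quiet_params <- function(params = base_params) {
  for (nm in c("prevalence", "growth_first_month", "growth_subsequent",
               "mort_undiag_malig", "prob_progression", "mort_biopsy",
               "biopsy_complication", "mort_surgery_malig",
               "mort_surgery_benign",
               grep("^mort_(distant|local|regional)_y", names(params), value = TRUE))) {
    params[[nm]] <- 0
  }
  params$stage_local <- 1
  params$stage_regional <- 0
  params
}

# all utilities set to 1, no discounting
unit_utility_config <- function(cfg = base_cfg) {
  cfg$discount_annual <- 0
  cfg
}

unit_utility_params <- function(params = base_params) {
  for (nm in grep("^u_age|^u_local|^u_regional|^u_distant", names(params),
                  value = TRUE)) {
    params[[nm]] <- 1
  }
  params
}
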