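# Shared fixtures: parameter sets with targeted overrides and simple
# analytic life tables. All built in code; no stored data.

# Base-case config as a nested list, with per-parameter overrides applied
# before validation. Overrides: name = list(mean=, sd=, ...) or name = scalar
# (mean only, sd 0) for uncertain parameters; model constants as scalars.
make_params <- function(...) {
  overrides <- list(...)
  cfg <- yaml::read_yaml(base_case_config())
  consts <- c("annual_discount", "wtp_per_qalm", "start_age_months",
              "horizon_cycles", "psa_iterations")
  for (nm in names(overrides)) {
    ov <- overrides[[nm]]
    if (nm %in% consts) {
      cfg$model[[nm]] <- ov
      next
    }
    placed <- FALSE
    for (section in c("probabilities", "utilities", "costs", "fees")) {
      if (nm %in% names(cfg[[section]])) {
        if (!is.list(ov)) ov <- list(mean = ov, sd = 0)
        cfg[[section]][[nm]] <- ov
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("unknown override: ", nm)
  }
  load_parameter_set(cfg)
}

# All failure probabilities zero, all utilities 1, discount 0: the cohort
# stays well and QALMs equal discounted life months.
degenerate_params <- function(discount = 0) {
  u1 <- list(mean = 1, sd = 0)
  make_params(p_fail_TKA = 0, p_fail_UKA = 0, p_fail_HTO = 0,
              u_well_TKA = u1, u_well_UKA = u1, u_well_HTO = u1,
              u_fail_TKA = u1, u_fail_UKA = u1, u_fail_HTO = u1,
              u_fail_instab = u1, u_post_rev1 = u1, u_tka_after_hto = u1,
              u_post_vvc = u1, annual_discount = discount)
}

zero_mortality_table <- function() life_table(45:90, rep(0, 46))

# constant monthly death probability p at every age
const_mortality_table <- function(p_monthly) {
  life_table(45:90, rep(1 - (1 - p_monthly)^12, 46))
}

general_table <- function() read_life_table(synthetic_life_table_path("general"))

uncertain_names <- c(
  "p_fail_TKA", "p_fail_UKA", "p_fail_HTO",
  "f_instab_TKA", "f_instab_UKA", "f_instab_HTO", "p_periop_death",
  "u_well_TKA", "u_well_UKA", "u_well_HTO",
  "u_fail_TKA", "u_fail_UKA", "u_fail_HTO",
  "u_fail_instab", "u_post_rev1", "u_tka_after_hto", "u_post_vvc",
  "fee_TKA", "fee_TKA_hw", "fee_UKA", "fee_HTO", "fee_revTKA",
  "cost_TKA", "cost_UKA", "cost_HTO", "cost_rev_primary", "cost_rev_vvc")
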