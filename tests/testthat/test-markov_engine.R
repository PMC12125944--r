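test_that("degenerate cohort reduces to the closed form", {
  ps <- degenerate_params()
  lt <- zero_mortality_table()
  for (s in c("TKA", "UKA", "HTO")) {
    model <- build_strategy_model(s, ps)
    r <- run_cohort(model, lt, ps)
    expect_equal(r$effect, 540, tolerance = 1e-10)
    expect_equal(r$cost, model$index_cost)
    # arm reduces to {WELL_PRIMARY, DEAD}
    occupied <- colnames(r$trace)[colSums(r$trace) > 0]
    expect_setequal(occupied, "WELL_PRIMARY")
  }
})

test_that("constant mortality matches the geometric-series closed form", {
  ps <- degenerate_params()
  lt <- const_mortality_table(0.01)
  r <- run_cohort(build_strategy_model("TKA", ps), lt, ps)
  # trapezoid-corrected sum of 0.99^t: sum_{t=0}^{539} - (1 - 0.99^540)/2
  s540 <- 0.99^540
  closed <- (1 - s540) / 0.01 - 0.5 * (1 - s540)
  expect_equal(r$effect, closed, tolerance = 1e-10)
  expect_lt(abs(closed - 99.06), 0.1)
  # and against a patient-level simulation
  ms <- microsim_oracle(build_strategy_model("TKA", ps), lt, ps,
                        n = 20000L, seed = 99)
  expect_lt(abs(ms$mean_effect - r$effect), 3 * ms$se_effect)
})

test_that("occupancy rows conserve the cohort and death is monotone", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  for (s in c("TKA", "UKA", "HTO")) {
    r <- run_cohort(build_strategy_model(s, ps), lt, ps)
    expect_equal(unname(rowSums(r$trace)), rep(1, 541), tolerance = 1e-10)
    expect_true(all(r$trace >= -1e-15))
    expect_true(all(diff(r$trace[, "DEAD"]) >= -1e-15))
    expect_equal(r$cost, r$index_cost + sum(r$accrual$disc_cost))
    expect_equal(r$effect, sum(r$accrual$disc_qalm))
  }
})

test_that("cohort engine agrees with the microsimulation oracle", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  for (s in c("TKA", "HTO")) {
    model <- build_strategy_model(s, ps)
    r <- run_cohort(model, lt, ps)
    ms <- microsim_oracle(model, lt, ps, n = 30000L, seed = 17)
    expect_lt(abs(ms$mean_effect - r$effect), 3 * ms$se_effect)
    expect_lt(abs(ms$mean_cost - r$cost), 3 * ms$se_cost)
  }
})

test_that("raising the discount rate lowers both cost and effect", {
  lt <- general_table()
  prev_c <- Inf; prev_e <- Inf
  for (d in c(0, 0.015, 0.05)) {
    ps <- make_params(annual_discount = d)
    r <- run_cohort(build_strategy_model("TKA", ps), lt, ps)
    if (is.finite(prev_c)) {
      expect_lt(r$cost, prev_c)
      expect_lt(r$effect, prev_e)
    }
    prev_c <- r$cost; prev_e <- r$effect
  }
})

test_that("raising any state utility never decreases effectiveness", {
  lt <- general_table()
  base <- base_case_parameters()
  r0 <- run_cohort(build_strategy_model("HTO", base), lt, base)
  for (nm in c("u_well_HTO", "u_fail_HTO", "u_tka_after_hto", "u_post_vvc")) {
    raised <- min(1, base[[nm]]$mean + 0.05)
    ps <- do.call(make_params, setNames(list(list(mean = raised, sd = 0)), nm))
    r <- run_cohort(build_strategy_model("HTO", ps), lt, ps)
    expect_gte(r$effect, r0$effect)
  }
})

test_that("within-cycle corrected effect lies between boundary accruals", {
  ps <- base_case_parameters()
  lt <- general_table()
  model <- build_strategy_model("UKA", ps)
  r <- run_cohort(model, lt, ps)
  u <- model$states$utility
  dm <- (1 + ps$annual_discount)^(-1 / 12)
  d <- dm^((0:539) + 0.5)
  su <- r$trace %*% u
  start_acc <- sum(su[1:540] * d)
  end_acc <- sum(su[2:541] * d)
  expect_gte(r$effect, min(start_acc, end_acc))
  expect_lte(r$effect, max(start_acc, end_acc))
})

test_that("survival and revision curves behave as required", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  model <- build_strategy_model("TKA", ps)
  r <- run_cohort(model, lt, ps)
  cv <- survival_and_revision_curves(r, model)
  expect_equal(cv$alive[1], 1)
  expect_equal(cv$cum_revised[1], 0)
  expect_true(all(diff(cv$alive) <= 1e-15))
  expect_true(all(diff(cv$cum_revised) >= -1e-15))
  # no failures -> no revisions ever
  ps0 <- degenerate_params()
  model0 <- build_strategy_model("TKA", ps0)
  cv0 <- survival_and_revision_curves(run_cohort(model0, lt, ps0), model0)
  expect_true(all(cv0$cum_revised == 0))
})

test_that("horizon and perioperative mortality are honoured", {
  lt <- general_table()
  ps <- make_params(horizon_cycles = 120)
  r <- run_cohort(build_strategy_model("TKA", ps), lt, ps)
  expect_equal(nrow(r$trace), 121)
  expect_error(run_cohort(build_strategy_model("TKA", make_params(horizon_cycles = 0)),
                          lt, make_params(horizon_cycles = 0)),
               "horizon")
  psd <- make_params(p_periop_death = list(mean = 0.1, sd = 0))
  rd <- run_cohort(build_strategy_model("TKA", psd), lt, psd)
  expect_equal(rd$trace[1, "DEAD"], 0.1)
  expect_equal(rd$index_cost, r$index_cost)
})
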