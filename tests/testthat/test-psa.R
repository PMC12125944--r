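# Small PSAs on the event-rich tiny fixture keep these checks fast while
# still exercising every pathway.

test_that("parameter sampling reproduces the requested moments", {
  ps <- base_case_parameters()
  others <- setdiff(uncertain_names, "u_well_TKA")
  set.seed(123)
  draws <- replicate(10000, sample_parameter_set(ps, freeze = others)$u_well_TKA$mean)
  expect_equal(mean(draws), 0.840, tolerance = 0.02)
  expect_equal(sd(draws), 0.150, tolerance = 0.05)
  # zero-sd and frozen parameters come back untouched
  frozen <- sample_parameter_set(ps, freeze = "all")
  for (nm in uncertain_names) expect_identical(frozen[[nm]]$mean, ps[[nm]]$mean)
  expect_identical(frozen$p_periop_death$mean, 0)
  set.seed(7); a <- sample_parameter_set(ps)
  set.seed(7); b <- sample_parameter_set(ps)
  expect_identical(a, b)
})

test_that("a frozen single-iteration PSA equals the deterministic run", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  res <- run_psa(ps, lt, n = 1, seed = 5, freeze = "all")
  det <- run_cohort(build_strategy_model("UKA", ps), lt, ps)
  expect_equal(res$means$cost[res$means$strategy == "UKA"], det$cost)
  expect_equal(res$means$effect[res$means$strategy == "UKA"], det$effect)
})

test_that("PSA is reproducible and keeps draws paired across strategies", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  r1 <- run_psa(ps, lt, n = 25, seed = 11)
  r2 <- run_psa(ps, lt, n = 25, seed = 11)
  expect_identical(r1$draws, r2$draws)
  r3 <- run_psa(ps, lt, n = 25, seed = 12)
  expect_false(identical(r1$draws$cost, r3$draws$cost))
})

test_that("PSA strategy means track the base-case run within Monte-Carlo error", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  res <- run_psa(ps, lt, n = 300, seed = 2)
  m <- kneecua:::psa_matrices(res)
  for (s in c("TKA", "UKA", "HTO")) {
    det <- run_cohort(build_strategy_model(s, ps), lt, ps)
    se_e <- sd(m$effect[, s]) / sqrt(res$n)
    se_c <- sd(m$cost[, s]) / sqrt(res$n)
    # moment-preserving beta/gamma parameterisations keep parameter means,
    # but the model response is mildly non-linear; allow 3 SE plus 1% drift
    expect_lt(abs(mean(m$effect[, s]) - det$effect),
              3 * se_e + 0.01 * det$effect)
    expect_lt(abs(mean(m$cost[, s]) - det$cost),
              3 * se_c + 0.01 * det$cost)
  }
})

test_that("optimal probabilities sum to one and honour ties", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  res <- run_psa(ps, lt, n = 40, seed = 3)
  for (w in c(0, 500, 4166.67)) {
    pr <- optimal_probabilities(res, w)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
    expect_true(all(pr >= 0))
  }
  one <- run_psa(ps, lt, n = 1, seed = 4)
  pr1 <- optimal_probabilities(one, 4166.67)
  expect_setequal(as.numeric(pr1), c(1, 0, 0))
  # a degenerate PSA makes the CEAC a step indicator
  froz <- run_psa(ps, lt, n = 3, seed = 6, freeze = "all")
  cv <- ceac(froz, c(0, 4166.67))
  expect_true(all(unlist(cv[, -1]) %in% c(0, 1)))
  expect_equal(unname(rowSums(cv[, -1])), rep(1, 2))
})

test_that("ICE scatter matches the pairwise NMB comparison", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  res <- run_psa(ps, lt, n = 60, seed = 8)
  sc <- ice_scatter(res, "TKA", "UKA", wtp = 4166.67)
  expect_equal(sum(sc$quadrants), 60)
  m <- kneecua:::psa_matrices(res)
  gains <- inmb(m$effect[, "UKA"], m$cost[, "UKA"],
                m$effect[, "TKA"], m$cost[, "TKA"], 4166.67)
  expect_equal(sc$frac_below_wtp, mean(gains > 0))
  same <- ice_scatter(res, "UKA", "UKA")
  expect_true(all(same$points$d_effect == 0 & same$points$d_cost == 0))
  expect_error(ice_scatter(res, "TKA", "PKA"), "not present")
})

test_that("NMB kernel densities normalise and reject degenerate samples", {
  ps <- fixture_parameter_set("tiny")
  lt <- general_table()
  res <- run_psa(ps, lt, n = 80, seed = 9)
  dens <- nmb_density(res)
  for (d in dens) {
    area <- sum(diff(d$nmb) * (head(d$density, -1) + tail(d$density, -1)) / 2)
    expect_equal(area, 1, tolerance = 1e-3)
  }
  froz <- run_psa(ps, lt, n = 3, seed = 10, freeze = "all")
  expect_error(nmb_density(froz), "zero variance")
})
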