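test_that("default SD is 20% of the absolute mean", {
  expect_equal(default_sd(0.84), 0.168)
  expect_equal(default_sd(0), 0)
  expect_equal(default_sd(8178), 1635.6)
  expect_equal(default_sd(-5), 1)
  expect_error(default_sd(Inf), "finite")
})

test_that("beta moment conversion matches a numerical-integration oracle", {
  # oracle: integrate the density with the returned shapes and recover the
  # requested mean and sd
  for (case in list(c(0.5, 0.3), c(0.84, 0.15), c(0.062, 0.0124))) {
    sh <- beta_from_moments(case[1], case[2])
    m <- integrate(function(x) x * dbeta(x, sh[["alpha"]], sh[["beta"]]),
                   0, 1, rel.tol = 1e-10)$value
    m2 <- integrate(function(x) x^2 * dbeta(x, sh[["alpha"]], sh[["beta"]]),
                    0, 1, rel.tol = 1e-10)$value
    expect_equal(m, case[1], tolerance = 1e-7)
    expect_equal(sqrt(m2 - m^2), case[2], tolerance = 1e-6)
  }
  sh <- beta_from_moments(0.5, 0.3)
  expect_equal(unname(sh), c(8 / 9, 8 / 9), tolerance = 1e-10)
  expect_error(beta_from_moments(0.5, 0.5), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "\\(0, 1\\)")
})

test_that("gamma moment conversion matches a sampling oracle", {
  sh <- gamma_from_moments(8010, 1738)
  expect_equal(unname(sh[1]), (8010 / 1738)^2, tolerance = 1e-12)
  set.seed(7)
  x <- rgamma(1e6, shape = sh[["shape"]], scale = sh[["scale"]])
  expect_equal(mean(x), 8010, tolerance = 0.01)
  expect_equal(sd(x), 1738, tolerance = 0.01)
  sh2 <- gamma_from_moments(14739, 2948)
  expect_equal(unname(sh2[1]), 24.99, tolerance = 1e-3)
  expect_equal(unname(sh2[2]), 589.7, tolerance = 1e-3)
  # shape-1 identity: mean = sd is the exponential
  expect_equal(unname(gamma_from_moments(250, 250)), c(1, 250))
  expect_error(gamma_from_moments(-1, 2), "> 0")
})

test_that("moment conversions round-trip for random feasible inputs", {
  set.seed(11)
  for (i in 1:50) {
    m <- runif(1, 0.01, 0.99)
    s <- sqrt(runif(1, 0.01, 0.99) * m * (1 - m))
    sh <- beta_from_moments(m, s)
    a <- sh[["alpha"]]; b <- sh[["beta"]]
    expect_equal(a / (a + b), m, tolerance = 1e-10)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), s, tolerance = 1e-10)
    mg <- runif(1, 1, 2e4); sg <- runif(1, 1, 5e3)
    shg <- gamma_from_moments(mg, sg)
    expect_equal(shg[["shape"]] * shg[["scale"]], mg, tolerance = 1e-10)
    expect_equal(sqrt(shg[["shape"]]) * shg[["scale"]], sg, tolerance = 1e-10)
  }
})

test_that("rate-probability conversion is exponential and self-inverse", {
  expect_equal(prob_from_rate(0, 1), 0)
  expect_equal(prob_from_rate(29.559e-4, 1), 1 - exp(-29.559e-4))
  expect_equal(prob_from_rate(29.559e-4, 1), 0.0029515, tolerance = 1e-4)
  # memorylessness: two half-steps on survivors equal one full step
  r <- 0.013; p_full <- prob_from_rate(r, 2)
  p_half <- prob_from_rate(r, 1)
  expect_equal(1 - (1 - p_half)^2, p_full, tolerance = 1e-14)
  set.seed(3)
  p <- runif(20, 0.001, 0.999)
  expect_equal(prob_from_rate(rate_from_prob(p)), p, tolerance = 1e-12)
  expect_error(prob_from_rate(-0.1), ">= 0")
})

test_that("failure splitting conserves the total probability", {
  sp <- split_failure(29.559e-4, 0.124)
  expect_equal(unname(sp), c(25.894e-4, 3.665e-4), tolerance = 1e-4)
  expect_equal(sum(sp), 29.559e-4)
  expect_equal(split_failure(0.3, 0), c(no_instab = 0.3, instab = 0))
  expect_equal(split_failure(0.3, 1), c(no_instab = 0, instab = 0.3))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(1); f <- runif(1)
    expect_identical(sum(split_failure(p, f)), p * (1 - f) + p * f)
  }
})

test_that("the bundled base case loads with every published value intact", {
  ps <- base_case_parameters()
  expect_s3_class(ps, "parameter_set")
  expect_equal(ps$cost_TKA$mean, 8010)
  expect_equal(ps$cost_TKA$sd, 1738)
  expect_equal(ps$cost_TKA$family, "gamma")
  expect_equal(ps$p_fail_UKA$mean, 8.1627e-4)
  expect_equal(ps$u_well_UKA$mean, 0.870)
  expect_equal(ps$u_well_UKA$family, "beta")
  expect_equal(ps$f_instab_HTO$low, 0.076)
  expect_equal(ps$wtp_per_qalm, 4166.67)
  expect_equal(ps$annual_discount, 0.015)
  expect_equal(ps$horizon_cycles, 540)
  # invariants across the whole set
  for (nm in uncertain_names) {
    uv <- ps[[nm]]
    expect_gte(uv$sd, 0)
    expect_lte(uv$low, uv$mean)
    expect_gte(uv$high, uv$mean)
    if (uv$family == "beta") expect_true(uv$mean >= 0 && uv$mean <= 1)
    if (uv$family == "gamma") expect_gte(uv$mean, 0)
  }
})

test_that("config validation and defaulting rules apply on load", {
  # missing sd -> 20% of mean; missing range -> central 95% interval
  ps <- make_params(u_well_TKA = list(mean = 0.5))
  expect_equal(ps$u_well_TKA$sd, 0.1)
  sh <- beta_from_moments(0.5, 0.1)
  expect_equal(ps$u_well_TKA$low, qbeta(0.025, sh[["alpha"]], sh[["beta"]]))
  expect_error(make_params(u_well_TKA = list(mean = 1.3)),
               "u_well_TKA")
  cfg <- yaml::read_yaml(base_case_config())
  cfg$costs$cost_TKA <- NULL
  expect_error(load_parameter_set(cfg), "cost_TKA")
  expect_error(make_params(cost_TKA = list(mean = -10)), "cost_TKA")
})
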