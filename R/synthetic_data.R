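#' Gompertz-Makeham life-table generator
#'
#' Annual mortality follows `q(age) = min(1, (makeham + level * exp(slope *
#' age)) * sex_multiplier)`, the classical adult-mortality law: a small
#' age-independent background term plus exponentially increasing senescent
#' mortality. The defaults are calibrated (see
#' [gompertz_defaults()]) so that remaining life expectancy at age 45
#' matches published Canadian values — about 37.8 years for the general
#' population, with males shorter-lived (36.0) and females longer-lived
#' (39.6).
#'
#' @param makeham Age-independent annual hazard component, >= 0.
#' @param level Senescent component at age 0, > 0 per year.
#' @param slope Log-increase of senescent mortality per year of age, > 0.
#' @param sex_multiplier Proportional scaling of q, > 0.
#' @param sex Label for the generated table.
#' @return A [life_table()] covering ages 45..90.
#' @export
make_life_table <- function(makeham = 5e-4, level = 2.0e-5, slope = 0.095,
                            sex_multiplier = 1,
                            sex = c("general", "male", "female")) {
  sex <- match.arg(sex)
  if (makeham < 0 || level <= 0 || slope < 0 || sex_multiplier <= 0)
    stop("invalid Gompertz-Makeham parameters", call. = FALSE)
  ages <- 45:90
  q <- pmin(1, (makeham + level * exp(slope * ages)) * sex_multiplier)
  if (q[1L] >= 1)
    stop("calibration error: q(45) >= 1 under these parameters", call. = FALSE)
  life_table(ages, q, sex = sex)
}

#' Calibrated Gompertz-Makeham defaults per sex
#'
#' The `level` parameter for each sex solves for a target remaining life
#' expectancy at age 45 (general 37.8, male 36.0, female 39.6 years,
#' Canadian period life-table values), with `makeham = 5e-4` and
#' `slope = 0.095` fixed at typical adult-mortality values.
#'
#' @param sex One of `"general"`, `"male"`, `"female"`.
#' @return List of parameters accepted by [make_life_table()].
#' @export
gompertz_defaults <- function(sex = c("general", "male", "female")) {
  sex <- match.arg(sex)
  target <- c(general = 37.8, male = 36.0, female = 39.6)[[sex]]
  makeham <- 5e-4; slope <- 0.095
  f <- function(level)
    gm_life_expectancy(makeham, level, slope) - target
  level <- stats::uniroot(f, c(1e-8, 5e-4), tol = 1e-14)$root
  list(makeham = makeham, level = level, slope = slope,
       sex_multiplier = 1, sex = sex)
}

# Remaining life expectancy at 45 under the (uncapped-to-110) GM law,
# by direct survival summation on annual steps.
gm_life_expectancy <- function(makeham, level, slope, max_age = 110) {
  ages <- 45:max_age
  q <- pmin(1, makeham + level * exp(slope * ages))
  surv <- cumprod(1 - q)
  sum(surv) + 0.5  # half-year credit for the year of death
}

#' Synthetic Canadian-calibrated life table
#'
#' @param sex One of `"general"`, `"male"`, `"female"`.
#' @return A [life_table()] from [make_life_table()] with the calibrated
#'   defaults for that sex.
#' @export
synthetic_life_table <- function(sex = c("general", "male", "female")) {
  sex <- match.arg(sex)
  do.call(make_life_table, gompertz_defaults(sex))
}

#' Path to a bundled synthetic life-table CSV
#'
#' The bundled files were generated by [synthetic_life_table()] and are
#' synthetic stand-ins for national life tables, not observed data.
#'
#' @param sex One of `"general"`, `"male"`, `"female"`.
#' @return File path.
#' @export
synthetic_life_table_path <- function(sex = c("general", "male", "female")) {
  sex <- match.arg(sex)
  system.file("extdata", paste0("lifetable_synthetic_", sex, ".csv"),
              package = "kneecua", mustWork = TRUE)
}

#' Fixture parameter sets for testing
#'
#' `"base"` is the bundled base-case input table; `"tiny"` inflates all
#' monthly failure probabilities 50-fold so that revision pathways are
#' exercised heavily within short horizons.
#'
#' @param scale `"base"` or `"tiny"`.
#' @return A [parameter_set()].
#' @export
fixture_parameter_set <- function(scale = c("base", "tiny")) {
  scale <- match.arg(scale)
  ps <- base_case_parameters()
  if (scale == "tiny") {
    for (nm in c("p_fail_TKA", "p_fail_UKA", "p_fail_HTO")) {
      m <- min(ps[[nm]]$mean * 50, 1)
      ps[[nm]] <- uncertain_value(m, sd = min(0.2 * m, 0.99 * sqrt(m * (1 - m))),
                                  family = "beta")
    }
    class(ps) <- "parameter_set"
  }
  ps
}

#' Individual-level microsimulation oracle
#'
#' Simulates `n` independent patient trajectories under exactly the cohort
#' engine's transition rules and accrual conventions (half-cycle utility
#' credit discounted at mid-cycle, entry costs at the arrival cycle, index
#' cost at cycle 0). The cohort engine computes the expectation of this
#' process, so for large `n` the two must agree within Monte-Carlo error;
#' this is the package's primary internal validity check.
#'
#' @param model A [build_strategy_model()] result.
#' @param table A [life_table()].
#' @param params A [parameter_set()].
#' @param n Number of simulated patients.
#' @param seed RNG seed.
#' @return List with `mean_cost`, `mean_effect`, `se_cost`, `se_effect`, `n`.
#' @export
microsim_oracle <- function(model, table, params, n = 10000L, seed = 1L) {
  stopifnot(inherits(model, "strategy_model"), n >= 1)
  set.seed(seed)
  H <- as.integer(params$horizon_cycles)
  a0 <- as.integer(params$start_age_months)
  disc_m <- (1 + params$annual_discount)^(-1 / 12)
  states <- .STATES
  ns <- length(states)
  dead <- match("DEAD", states)

  years <- unique((a0 + 0:(H - 1)) %/% 12L)
  P_year <- lapply(years, function(y) transition_matrix(model, y * 12L, table))
  names(P_year) <- as.character(years)

  u <- model$states$utility
  ec <- model$states$entry_cost
  transient <- which(model$states$transient)

  p_periop <- params$p_periop_death$mean
  state <- rep.int(match("WELL_PRIMARY", states), n)
  if (p_periop > 0) {
    state[stats::runif(n) < p_periop] <- dead
  }
  cost <- rep.int(model$index_cost, n)
  effect <- numeric(n)

  for (t in 0:(H - 1L)) {
    alive <- which(state != dead)
    if (!length(alive)) break
    P <- P_year[[as.character((a0 + t) %/% 12L)]]
    new_state <- state
    for (s in unique(state[alive])) {
      idx <- alive[state[alive] == s]
      new_state[idx] <- sample.int(ns, length(idx), replace = TRUE,
                                   prob = P[s, ])
    }
    effect <- effect + 0.5 * (u[state] + u[new_state]) * disc_m^(t + 0.5)
    arrived <- which(new_state %in% transient)
    if (length(arrived))
      cost[arrived] <- cost[arrived] + ec[new_state[arrived]] * disc_m^(t + 1)
    state <- new_state
  }
  list(mean_cost = mean(cost), mean_effect = mean(effect),
       se_cost = stats::sd(cost) / sqrt(n),
       se_effect = stats::sd(effect) / sqrt(n), n = n)
}
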