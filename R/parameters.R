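#' Uncertain model input
#'
#' A point estimate together with its uncertainty specification: standard
#' deviation, plausible range for deterministic sensitivity analysis, and the
#' distribution family used when the parameter is sampled in probabilistic
#' sensitivity analysis.
#'
#' @param mean Point estimate (native units).
#' @param sd Standard deviation, same units; `NULL` applies the 20%-of-mean
#'   default via [default_sd()].
#' @param low,high Plausible-range bounds; `NULL` defaults to the central 95%
#'   interval of the assigned distribution (or the mean itself when `sd = 0`).
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @return An object of class `uncertain_value`.
#' @export
uncertain_value <- function(mean, sd = NULL, low = NULL, high = NULL,
                            family = c("beta", "gamma", "fixed")) {
  family <- match.arg(family)
  if (!is.finite(mean)) stop("mean must be finite", call. = FALSE)
  if (is.null(sd)) sd <- default_sd(mean)
  if (!is.finite(sd) || sd < 0) stop("sd must be finite and >= 0", call. = FALSE)
  if (family == "beta") {
    if (mean < 0 || mean > 1)
      stop("beta-family mean must lie in [0, 1], got ", mean, call. = FALSE)
    if (sd > 0 && sd^2 >= mean * (1 - mean))
      stop("infeasible beta moments: sd^2 >= mean*(1-mean) for mean ", mean,
           call. = FALSE)
  }
  if (family == "gamma" && mean < 0)
    stop("gamma-family mean must be >= 0, got ", mean, call. = FALSE)
  if (is.null(low) || is.null(high)) {
    ci <- central_interval(mean, sd, family)
    if (is.null(low)) low <- ci[1L]
    if (is.null(high)) high <- ci[2L]
  }
  if (low > mean + 1e-12 || high < mean - 1e-12)
    stop("plausible range [", low, ", ", high, "] must contain the mean ",
         mean, call. = FALSE)
  structure(list(mean = mean, sd = sd, low = low, high = high,
                 family = family),
            class = "uncertain_value")
}

#' @export
print.uncertain_value <- function(x, ...) {
  cat(sprintf("<uncertain_value> mean %.6g sd %.6g [%.6g, %.6g] %s\n",
              x$mean, x$sd, x$low, x$high, x$family))
  invisible(x)
}

#' Default standard deviation rule
#'
#' Inputs whose source reports no dispersion receive an SD equal to 20% of
#' the absolute mean, the convention used to fill missing SDs in the input
#' table.
#'
#' @param mean Finite point estimate.
#' @return `0.2 * abs(mean)`.
#' @export
default_sd <- function(mean) {
  if (!is.finite(mean)) stop("mean must be finite", call. = FALSE)
  0.2 * abs(mean)
}

# Central 95% interval of the assigned sampling distribution; degenerate
# families collapse to the mean.
central_interval <- function(mean, sd, family) {
  if (sd == 0 || family == "fixed" || mean == 0 ||
      (family == "beta" && mean == 1)) {
    return(c(mean, mean))
  }
  if (family == "beta") {
    sh <- beta_from_moments(mean, sd)
    stats::qbeta(c(0.025, 0.975), sh[["alpha"]], sh[["beta"]])
  } else {
    sh <- gamma_from_moments(mean, sd)
    stats::qgamma(c(0.025, 0.975), shape = sh[["shape"]], scale = sh[["scale"]])
  }
}

#' Beta shape parameters from mean and standard deviation
#'
#' Method of moments: `nu = mean*(1-mean)/sd^2 - 1`, `alpha = mean*nu`,
#' `beta = (1-mean)*nu`. Feasibility requires `sd^2 < mean*(1-mean)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation > 0.
#' @return Named numeric vector `c(alpha =, beta =)`.
#' @export
beta_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly in (0, 1), got ", mean, call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop("infeasible beta moments: sd^2 = ", sd^2, " >= mean*(1-mean) = ",
         mean * (1 - mean), call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma shape/scale from mean and standard deviation
#'
#' Method of moments: `shape = (mean/sd)^2`, `scale = sd^2/mean`.
#'
#' @param mean Mean > 0.
#' @param sd Standard deviation > 0.
#' @return Named numeric vector `c(shape =, scale =)`.
#' @export
gamma_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("gamma mean must be > 0", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0", call. = FALSE)
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Convert a constant event rate to a transition probability
#'
#' Under exponential event times, `S(t) = exp(-rate * t)`, so the probability
#' of the event within `t` cycles is `1 - exp(-rate * t)`.
#'
#' @param rate Events per month, >= 0.
#' @param t Exposure in months, >= 0.
#' @return Probability in `[0, 1)`.
#' @export
prob_from_rate <- function(rate, t = 1) {
  if (any(!is.finite(rate)) || any(rate < 0))
    stop("rate must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and >= 0", call. = FALSE)
  -expm1(-rate * t)
}

#' Inverse of [prob_from_rate()]
#'
#' @param p Probability in `[0, 1)`.
#' @param t Exposure in months, > 0.
#' @return Rate per month.
#' @export
rate_from_prob <- function(p, t = 1) {
  if (any(p < 0) || any(p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  -log1p(-p) / t
}

#' Split a failure probability by instability involvement
#'
#' The instability fraction is the conditional probability that a failure
#' involves joint instability, so the two routes partition the total monthly
#' failure probability exactly.
#'
#' @param p_fail Monthly failure probability in `[0, 1]`.
#' @param f_instab Conditional instability fraction in `[0, 1]`.
#' @return Named vector `c(no_instab =, instab =)` summing to `p_fail`.
#' @export
split_failure <- function(p_fail, f_instab) {
  if (p_fail < 0 || p_fail > 1) stop("p_fail must lie in [0, 1]", call. = FALSE)
  if (f_instab < 0 || f_instab > 1) stop("f_instab must lie in [0, 1]", call. = FALSE)
  c(no_instab = p_fail * (1 - f_instab), instab = p_fail * f_instab)
}

# Field registry: (config section, distribution family, domain) per parameter.
# Probabilities and utilities sample as beta, costs and fees as gamma.
param_registry <- function() {
  prob <- c("p_fail_TKA", "p_fail_UKA", "p_fail_HTO",
            "f_instab_TKA", "f_instab_UKA", "f_instab_HTO",
            "p_periop_death")
  util <- c("u_well_TKA", "u_well_UKA", "u_well_HTO",
            "u_fail_TKA", "u_fail_UKA", "u_fail_HTO",
            "u_fail_instab", "u_post_rev1", "u_tka_after_hto", "u_post_vvc")
  fees <- c("fee_TKA", "fee_TKA_hw", "fee_UKA", "fee_HTO", "fee_revTKA")
  cost <- c("cost_TKA", "cost_UKA", "cost_HTO",
            "cost_rev_primary", "cost_rev_vvc")
  data.frame(
    name = c(prob, util, fees, cost),
    section = c(rep("probabilities", length(prob)),
                rep("utilities", length(util)),
                rep("fees", length(fees)),
                rep("costs", length(cost))),
    family = c(rep("beta", length(prob)), rep("beta", length(util)),
               rep("gamma", length(fees)), rep("gamma", length(cost))),
    stringsAsFactors = FALSE
  )
}

model_constant_defaults <- function() {
  list(annual_discount = 0.015, wtp_per_qalm = 4166.67,
       start_age_months = 540L, horizon_cycles = 540L,
       psa_iterations = 3000L)
}

#' Assemble and validate a full parameter set
#'
#' @param values Named list: each uncertain parameter maps to a list with
#'   elements `mean` and optionally `sd`, `low`, `high`; model constants
#'   (`annual_discount`, `wtp_per_qalm`, `start_age_months`,
#'   `horizon_cycles`, `psa_iterations`) map to scalars.
#' @return An object of class `parameter_set`: uncertain values plus model
#'   constants.
#' @export
parameter_set <- function(values) {
  reg <- param_registry()
  out <- list()
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    v <- values[[nm]]
    if (is.null(v) || is.null(v$mean)) {
      if (nm == "p_periop_death") {
        # named as an event in the model description but given no value;
        # defaults to zero so only background mortality applies
        v <- list(mean = 0, sd = 0)
      } else {
        stop("configuration error: missing mean for parameter '", nm, "'",
             call. = FALSE)
      }
    }
    uv <- tryCatch(
      uncertain_value(v$mean, sd = v$sd, low = v$low, high = v$high,
                      family = reg$family[i]),
      error = function(e) {
        stop("validation error for parameter '", nm, "': ",
             conditionMessage(e), call. = FALSE)
      })
    out[[nm]] <- uv
  }
  const <- model_constant_defaults()
  for (nm in names(const)) {
    if (!is.null(values[[nm]])) const[[nm]] <- values[[nm]]
  }
  if (const$horizon_cycles <= 0) stop("horizon_cycles must be > 0", call. = FALSE)
  if (const$annual_discount < 0) stop("annual_discount must be >= 0", call. = FALSE)
  structure(c(out, const), class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  reg <- param_registry()
  cat("<parameter_set>", nrow(reg), "uncertain parameters\n")
  cat(sprintf("  discount %.3f/yr, WTP %.2f CAD/QALM, horizon %d cycles, start age %d months\n",
              x$annual_discount, x$wtp_per_qalm, x$horizon_cycles,
              x$start_age_months))
  invisible(x)
}

#' Load a parameter set from a YAML or JSON config file
#'
#' The file mirrors the input table: sections `probabilities`, `utilities`,
#' `costs`, `fees` hold per-parameter `mean` (and optional `sd`, `low`,
#' `high`); a `model` section holds the fixed constants. Missing SDs default
#' to 20% of the mean; missing ranges default to the central 95% interval of
#' the assigned distribution.
#'
#' @param config_source Path to a `.yaml`/`.yml`/`.json` file, or an
#'   already-parsed nested list of the same shape.
#' @return A [parameter_set()].
#' @export
load_parameter_set <- function(config_source) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source))
      stop("config file not found: ", config_source, call. = FALSE)
    if (grepl("\\.json$", config_source, ignore.case = TRUE)) {
      jsonlite::read_json(config_source, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else {
      yaml::read_yaml(config_source)
    }
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a file path or a list", call. = FALSE)
  }
  values <- list()
  for (section in c("probabilities", "utilities", "costs", "fees")) {
    sec <- cfg[[section]]
    if (is.null(sec)) next
    for (nm in names(sec)) {
      entry <- sec[[nm]]
      if (!is.list(entry)) entry <- list(mean = entry)
      values[[nm]] <- entry
    }
  }
  for (nm in names(cfg$model)) values[[nm]] <- cfg$model[[nm]]
  parameter_set(values)
}

#' Path to the bundled base-case configuration
#'
#' @return Path to `table1.yaml` shipped with the package.
#' @export
base_case_config <- function() {
  system.file("extdata", "table1.yaml", package = "kneecua", mustWork = TRUE)
}

#' The base-case parameter set
#'
#' Convenience wrapper: loads the bundled base-case config.
#'
#' @return A [parameter_set()].
#' @export
base_case_parameters <- function() {
  load_parameter_set(base_case_config())
}
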