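#' Draw one random parameter set
#'
#' Utilities and probability-type parameters are drawn from beta
#' distributions, costs and provider fees from gamma distributions, each
#' parameterised by method of moments from its mean and SD. Parameters with
#' `sd = 0` (and the model constants: discount rate, WTP, horizon, start
#' age) are left at their base-case values. Draws are independent across
#' parameters.
#'
#' @param params A [parameter_set()].
#' @param freeze Character vector of parameter names to hold at their means
#'   (e.g. the probability parameters), or `"all"`.
#' @return A `parameter_set` whose uncertain values carry the drawn means
#'   (with `sd = 0`).
#' @export
sample_parameter_set <- function(params, freeze = character()) {
  stopifnot(inherits(params, "parameter_set"))
  reg <- param_registry()
  out <- params
  freeze_all <- length(freeze) == 1L && identical(freeze, "all")
  for (i in seq_len(nrow(reg))) {
    nm <- reg$name[i]
    uv <- params[[nm]]
    if (uv$sd == 0 || freeze_all || nm %in% freeze) next
    drawn <- if (reg$family[i] == "beta") {
      sh <- beta_from_moments(uv$mean, uv$sd)
      stats::rbeta(1L, sh[["alpha"]], sh[["beta"]])
    } else {
      sh <- gamma_from_moments(uv$mean, uv$sd)
      stats::rgamma(1L, shape = sh[["shape"]], scale = sh[["scale"]])
    }
    out[[nm]] <- structure(list(mean = drawn, sd = 0, low = drawn,
                                high = drawn, family = uv$family),
                           class = "uncertain_value")
  }
  class(out) <- "parameter_set"
  out
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: for each iteration one random parameter set is
#' drawn and the full cohort model is run for all three strategies under
#' that shared draw (required for paired incremental analysis). Fully
#' reproducible given `seed`.
#'
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param n Iterations (defaults to the parameter set's `psa_iterations`).
#' @param seed RNG seed.
#' @param freeze Passed to [sample_parameter_set()].
#' @return An object of class `psa_result`: data.frame `draws` with columns
#'   `iteration`, `strategy`, `cost`, `effect`; per-strategy `means`; `n`;
#'   `seed`; `wtp` from the parameter set.
#' @export
run_psa <- function(params, table, n = NULL, seed = 1L, freeze = character()) {
  stopifnot(inherits(params, "parameter_set"), inherits(table, "life_table"))
  if (is.null(n)) n <- params$psa_iterations
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  strategies <- c("TKA", "UKA", "HTO")
  cost <- matrix(NA_real_, n, 3L, dimnames = list(NULL, strategies))
  effect <- cost
  for (it in seq_len(n)) {
    ps_it <- sample_parameter_set(params, freeze = freeze)
    for (s in strategies) {
      r <- run_cohort(build_strategy_model(s, ps_it), table, ps_it)
      cost[it, s] <- r$cost
      effect[it, s] <- r$effect
    }
  }
  draws <- data.frame(
    iteration = rep(seq_len(n), times = 3L),
    strategy = rep(strategies, each = n),
    cost = as.vector(cost), effect = as.vector(effect))
  means <- data.frame(strategy = strategies,
                      cost = colMeans(cost), effect = colMeans(effect))
  rownames(means) <- NULL
  structure(list(draws = draws, means = means, n = n, seed = seed,
                 wtp = params$wtp_per_qalm),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d)\n", x$n, x$seed))
  print(x$means, row.names = FALSE)
  invisible(x)
}

# iteration x strategy matrices from the long draw store
psa_matrices <- function(res) {
  d <- res$draws
  strategies <- unique(d$strategy)
  f <- function(col) {
    m <- sapply(strategies, function(s) d[[col]][d$strategy == s])
    matrix(m, ncol = length(strategies),
           dimnames = list(NULL, strategies))
  }
  list(cost = f("cost"), effect = f("effect"))
}

#' Probability each strategy is optimal at a willingness to pay
#'
#' Per iteration the strategy with the highest NMB scores 1 (exact ties
#' split equally); probabilities average over iterations and sum to 1.
#'
#' @param res A [run_psa()] result.
#' @param wtp Willingness to pay, CAD per QALM.
#' @return Named numeric vector of probabilities.
#' @export
optimal_probabilities <- function(res, wtp) {
  stopifnot(inherits(res, "psa_result"))
  m <- psa_matrices(res)
  benefit <- m$effect * wtp - m$cost
  best <- benefit == apply(benefit, 1L, max)
  score <- best / rowSums(best)
  colMeans(score)
}

#' Cost-effectiveness acceptability curves
#'
#' Evaluates [optimal_probabilities()] on a WTP grid. The default grid runs
#' 0 to 10,000 CAD/QALM in steps of 100 with 500 and the base-case threshold
#' 4,166.67 inserted.
#'
#' @param res A [run_psa()] result.
#' @param wtp_grid Numeric vector of WTP values.
#' @return data.frame with columns `wtp` and one probability column per
#'   strategy; probabilities sum to 1 per row.
#' @export
ceac <- function(res, wtp_grid = default_wtp_grid()) {
  stopifnot(inherits(res, "psa_result"), length(wtp_grid) >= 1)
  probs <- t(vapply(wtp_grid, function(w) optimal_probabilities(res, w),
                    numeric(3L)))
  out <- data.frame(wtp = wtp_grid, probs)
  names(out)[-1L] <- colnames(probs)
  out
}

#' Default willingness-to-pay grid
#' @return Sorted numeric vector, 0..10,000 by 100 plus 500 and 4,166.67.
#' @export
default_wtp_grid <- function() {
  sort(unique(c(seq(0, 10000, by = 100), 500, 4166.67)))
}

#' Incremental cost-effectiveness scatter
#'
#' Per-iteration incremental pairs of a comparator against a reference, with
#' quadrant counts and the fraction of iterations falling below (acceptable
#' at) the WTP line.
#'
#' @param res A [run_psa()] result.
#' @param reference,comparator Strategy names.
#' @param wtp Willingness to pay for the acceptability fraction.
#' @return List: `points` (data.frame `iteration`, `d_effect`, `d_cost`),
#'   `quadrants` (named counts NE/NW/SE/SW), `frac_below_wtp`.
#' @export
ice_scatter <- function(res, reference = "TKA", comparator = "UKA",
                        wtp = res$wtp) {
  stopifnot(inherits(res, "psa_result"))
  m <- psa_matrices(res)
  if (!all(c(reference, comparator) %in% colnames(m$cost)))
    stop("strategy not present in PSA result", call. = FALSE)
  de <- m$effect[, comparator] - m$effect[, reference]
  dc <- m$cost[, comparator] - m$cost[, reference]
  quad <- c(NE = sum(de >= 0 & dc >= 0), NW = sum(de < 0 & dc >= 0),
            SE = sum(de >= 0 & dc < 0), SW = sum(de < 0 & dc < 0))
  list(points = data.frame(iteration = seq_along(de), d_effect = de,
                           d_cost = dc),
       quadrants = quad,
       frac_below_wtp = mean(de * wtp - dc > 0))
}

#' Kernel density of NMB per strategy
#'
#' Gaussian kernel density of the per-iteration NMB distribution, using the
#' standard plug-in bandwidth (`stats::bw.nrd0`).
#'
#' @param res A [run_psa()] result.
#' @param wtp Willingness to pay.
#' @param bw Bandwidth rule or value, passed to [stats::density()].
#' @return Named list per strategy of data.frames `nmb`, `density`.
#' @export
nmb_density <- function(res, wtp = res$wtp, bw = "nrd0") {
  stopifnot(inherits(res, "psa_result"))
  if (res$n < 2L) stop("need at least 2 iterations", call. = FALSE)
  m <- psa_matrices(res)
  benefit <- m$effect * wtp - m$cost
  out <- lapply(colnames(benefit), function(s) {
    x <- benefit[, s]
    if (stats::sd(x) == 0)
      stop("degenerate NMB sample for ", s, ": zero variance", call. = FALSE)
    d <- stats::density(x, bw = bw)
    data.frame(nmb = d$x, density = d$y)
  })
  names(out) <- colnames(benefit)
  out
}

#' Write the PSA draw store as CSV
#'
#' @param res A [run_psa()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psa <- function(res, path) {
  utils::write.csv(res$draws, path, row.names = FALSE)
  invisible(path)
}
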