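#' Deterministic sensitivity-analysis range for a parameter
#'
#' Utilities default to the central 95% interval of their beta distribution
#' (their published plausible range of 0-1 is uninformative); probabilities,
#' costs and fees use their published plausible ranges.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @param grid_size Evaluation grid size (>= 2).
#' @return List `name`, `low`, `high`, `grid_size` of class `dsa_range`.
#' @export
dsa_range <- function(params, name, grid_size = 21L) {
  stopifnot(inherits(params, "parameter_set"))
  uv <- params[[name]]
  if (is.null(uv) || !inherits(uv, "uncertain_value"))
    stop("unknown parameter '", name, "'; valid names: ",
         paste(param_registry()$name, collapse = ", "), call. = FALSE)
  low <- uv$low; high <- uv$high
  if (uv$family == "beta") { low <- max(0, low); high <- min(1, high) }
  if (low >= high)
    stop("degenerate DSA range for '", name, "'", call. = FALSE)
  structure(list(name = name, low = low, high = high,
                 grid_size = as.integer(grid_size)),
            class = "dsa_range")
}

# Deterministic model evaluation with one (or more) parameter means
# overridden; returns the league-table inputs for all three strategies.
run_at <- function(params, table, overrides = list()) {
  ps <- params
  for (nm in names(overrides)) {
    if (nm %in% names(model_constant_defaults())) {
      ps[[nm]] <- overrides[[nm]]
    } else {
      uv <- ps[[nm]]
      if (is.null(uv)) stop("unknown parameter '", nm, "'", call. = FALSE)
      v <- overrides[[nm]]
      ps[[nm]] <- structure(list(mean = v, sd = uv$sd, low = min(uv$low, v),
                                 high = max(uv$high, v), family = uv$family),
                            class = "uncertain_value")
    }
  }
  class(ps) <- "parameter_set"
  out <- lapply(c("TKA", "UKA", "HTO"), function(s)
    run_cohort(build_strategy_model(s, ps), table, ps))
  data.frame(strategy = vapply(out, `[[`, character(1), "strategy"),
             cost = vapply(out, `[[`, numeric(1), "cost"),
             effect = vapply(out, `[[`, numeric(1), "effect"))
}

#' Incremental NMB of one strategy over another as a DSA metric
#'
#' @param a,b Strategy names.
#' @param wtp Willingness to pay; `NULL` uses the parameter set's value.
#' @return A function `(params, table, overrides)` -> INMB in CAD, suitable
#'   for [one_way_scan()], [tornado()] and [threshold_find()].
#' @export
inmb_metric <- function(a = "UKA", b = "TKA", wtp = NULL) {
  function(params, table, overrides = list()) {
    w <- if (is.null(wtp)) params$wtp_per_qalm else wtp
    pts <- run_at(params, table, overrides)
    ia <- match(a, pts$strategy); ib <- match(b, pts$strategy)
    inmb(pts$effect[ia], pts$cost[ia], pts$effect[ib], pts$cost[ib], w)
  }
}

#' One-way deterministic sensitivity scan
#'
#' Evaluates a metric over a parameter's grid with all other parameters at
#' their base-case means. Deterministic: no sampling.
#'
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param range A [dsa_range()].
#' @param metric A metric function as produced by [inmb_metric()].
#' @return data.frame with columns `value`, `metric`.
#' @export
one_way_scan <- function(params, table, range, metric = inmb_metric()) {
  stopifnot(inherits(range, "dsa_range"))
  grid <- seq(range$low, range$high, length.out = range$grid_size)
  vals <- vapply(grid, function(v)
    metric(params, table, stats::setNames(list(v), range$name)), numeric(1))
  data.frame(value = grid, metric = vals)
}

#' Tornado analysis
#'
#' Evaluates the metric at the low and high end of each parameter's DSA
#' range and orders parameters by descending spread.
#'
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param names Parameters to include; defaults to every uncertain parameter
#'   with a non-degenerate range.
#' @param metric Metric function, default INMB(UKA, TKA) at the base WTP.
#' @return data.frame of class `tornado`: `parameter`, `low`, `high`,
#'   `metric_low`, `metric_high`, `spread`, sorted by descending spread;
#'   `base_metric` attribute holds the all-base-case value.
#' @export
tornado <- function(params, table, names = NULL, metric = inmb_metric()) {
  if (is.null(names)) {
    reg <- param_registry()$name
    names <- reg[vapply(reg, function(nm) {
      uv <- params[[nm]]
      uv$sd > 0 && uv$high > uv$low
    }, logical(1))]
  }
  rows <- lapply(names, function(nm) {
    r <- dsa_range(params, nm)
    m_lo <- metric(params, table, stats::setNames(list(r$low), nm))
    m_hi <- metric(params, table, stats::setNames(list(r$high), nm))
    data.frame(parameter = nm, low = r$low, high = r$high,
               metric_low = m_lo, metric_high = m_hi,
               spread = abs(m_hi - m_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_metric") <- metric(params, table)
  class(out) <- c("tornado", "data.frame")
  out
}

#' Threshold (break-even) finding
#'
#' Bisection root of `metric(parameter value) = 0` inside a bracket, to a
#' tolerance of 1e-4 on the parameter scale.
#'
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param name Parameter to vary.
#' @param bracket Length-2 numeric; the metric must change sign across it.
#' @param metric Metric function, default INMB(UKA, TKA).
#' @param tol Root tolerance, default `1e-4`.
#' @return Parameter value at which the metric crosses zero.
#' @export
threshold_find <- function(params, table, name, bracket,
                           metric = inmb_metric(), tol = 1e-4) {
  f <- function(v) metric(params, table, stats::setNames(list(v), name))
  f_lo <- f(bracket[1L]); f_hi <- f(bracket[2L])
  if (is.na(f_lo) || is.na(f_hi) || sign(f_lo) == sign(f_hi))
    stop("bracket error: metric does not change sign over [",
         bracket[1L], ", ", bracket[2L], "]", call. = FALSE)
  stats::uniroot(f, bracket, f.lower = f_lo, f.upper = f_hi, tol = tol)$root
}

#' Two-way deterministic sensitivity map
#'
#' Runs the deterministic model on a grid over two parameters and records
#' the NMB-optimal strategy at each point (ties broken by higher
#' effectiveness).
#'
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param name_x,name_y Parameter names.
#' @param grid_x,grid_y Numeric grids (within each parameter's domain).
#' @param wtp Willingness to pay; `NULL` uses the parameter set's value.
#' @return data.frame with columns `x`, `y`, `optimal`.
#' @export
two_way_map <- function(params, table, name_x, name_y, grid_x, grid_y,
                        wtp = NULL) {
  w <- if (is.null(wtp)) params$wtp_per_qalm else wtp
  grid <- expand.grid(x = grid_x, y = grid_y)
  opt <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ov <- stats::setNames(list(grid$x[i], grid$y[i]), c(name_x, name_y))
    pts <- run_at(params, table, ov)
    benefit <- nmb(pts$effect, pts$cost, w)
    best <- which(benefit == max(benefit))
    if (length(best) > 1L) best <- best[which.max(pts$effect[best])]
    opt[i] <- pts$strategy[best]
  }
  grid$optimal <- opt
  grid
}
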