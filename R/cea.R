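#' Net monetary benefit
#'
#' `NMB = E * WTP - C`.
#'
#' @param effect Effectiveness in QALMs (vectorised).
#' @param cost Cost in CAD.
#' @param wtp Willingness to pay, CAD per QALM.
#' @return NMB in CAD.
#' @export
nmb <- function(effect, cost, wtp) {
  if (any(!is.finite(effect)) || any(!is.finite(cost)) || !is.finite(wtp))
    stop("nmb requires finite inputs", call. = FALSE)
  effect * wtp - cost
}

#' Incremental net monetary benefit
#'
#' `INMB(a, b) = NMB(a) - NMB(b)`; positive iff `a` is the more
#' cost-effective strategy at the given willingness to pay.
#'
#' @param effect_a,cost_a Effect and cost of strategy a.
#' @param effect_b,cost_b Effect and cost of strategy b.
#' @param wtp Willingness to pay, CAD per QALM.
#' @return INMB in CAD.
#' @export
inmb <- function(effect_a, cost_a, effect_b, cost_b, wtp) {
  nmb(effect_a, cost_a, wtp) - nmb(effect_b, cost_b, wtp)
}

#' League table with dominance classification and ICERs
#'
#' Strategies are ordered by ascending cost. A strategy is absolutely
#' dominated when another strategy is no more costly and no less effective
#' (with at least one strict inequality; cost ties are broken by
#' effectiveness). ICERs are computed between successive undominated
#' strategies. Extended dominance (a strategy bypassed by a mixture of two
#' others, detected as ICER non-monotonicity) can be enabled; it is off by
#' default.
#'
#' @param points data.frame with columns `strategy`, `cost`, `effect` (one
#'   row per strategy), or a list of [run_cohort()] results.
#' @param wtp Willingness to pay, CAD per QALM (for the NMB column).
#' @param extended Also flag extended dominance? Default `FALSE`.
#' @return data.frame of class `league_table`, ordered by cost, with columns
#'   `strategy`, `cost`, `incr_cost`, `effect`, `incr_effect`, `icer`, `nmb`,
#'   `dominance`, `icer_quadrant`.
#' @export
league_table <- function(points, wtp, extended = FALSE) {
  if (is.list(points) && !is.data.frame(points) &&
      all(vapply(points, inherits, logical(1), "run_result"))) {
    points <- data.frame(
      strategy = vapply(points, `[[`, character(1), "strategy"),
      cost = vapply(points, `[[`, numeric(1), "cost"),
      effect = vapply(points, `[[`, numeric(1), "effect"))
  }
  stopifnot(is.data.frame(points),
            all(c("strategy", "cost", "effect") %in% names(points)))
  if (nrow(points) < 2L) stop("need at least 2 strategies", call. = FALSE)
  if (anyDuplicated(points$strategy))
    stop("duplicate strategy names", call. = FALSE)
  if (any(!is.finite(points$cost)) || any(!is.finite(points$effect)))
    stop("costs and effects must be finite", call. = FALSE)

  df <- points[order(points$cost, -points$effect), , drop = FALSE]
  n <- nrow(df)
  df$dominance <- "undominated"
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
          (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])) {
        df$dominance[i] <- "absolutely_dominated"
        break
      }
    }
  }
  if (extended) {
    repeat {
      idx <- which(df$dominance == "undominated")
      if (length(idx) < 3L) break
      ic <- diff(df$cost[idx]) / diff(df$effect[idx])
      bad <- which(diff(ic) < 0)
      if (!length(bad)) break
      df$dominance[idx[bad[1L] + 1L]] <- "extendedly_dominated"
    }
  }

  df$incr_cost <- NA_real_; df$incr_effect <- NA_real_
  df$icer <- NA_real_; df$icer_quadrant <- NA_character_
  idx <- which(df$dominance == "undominated")
  if (length(idx) >= 2L) {
    for (k in 2:length(idx)) {
      i <- idx[k]; j <- idx[k - 1L]
      dc <- df$cost[i] - df$cost[j]
      de <- df$effect[i] - df$effect[j]
      df$incr_cost[i] <- dc
      df$incr_effect[i] <- de
      df$icer[i] <- if (de == 0) NA_real_ else dc / de
      df$icer_quadrant[i] <-
        if (de == 0) "no_effect_difference"
        else if (dc >= 0 && de > 0) "north_east"
        else if (dc < 0 && de > 0) "south_east"
        else if (dc < 0 && de < 0) "south_west"
        else "north_west"
    }
  }
  df$nmb <- nmb(df$effect, df$cost, wtp)
  out <- df[, c("strategy", "cost", "incr_cost", "effect", "incr_effect",
                "icer", "nmb", "dominance", "icer_quadrant")]
  rownames(out) <- NULL
  attr(out, "wtp") <- wtp
  class(out) <- c("league_table", "data.frame")
  out
}

#' @export
print.league_table <- function(x, ...) {
  cat("League table (WTP", format(attr(x, "wtp"), big.mark = ","),
      "CAD/QALM)\n")
  print.data.frame(x, digits = 6, row.names = FALSE)
  invisible(x)
}

#' Write a league table to CSV
#'
#' @param lt A [league_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_league_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}
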