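#' @name model_structure
#' @title Health-state structure of the three surgical strategies
#'
#' @description
#' Each strategy is a small state machine. The cohort starts well after the
#' index surgery. Failures are split into instability and non-instability
#' routes and are modelled as one-cycle transient surgery states: the
#' revision cost is charged on entry, the failure utility applies for that
#' single month, and survivors move to the post-operative well state.
#' Non-instability failure is revised with a primary prosthesis; instability
#' failure (and any failure after a first revision) is revised with a
#' varus-valgus constrained (VVC) prosthesis, after which no further surgery
#' is modelled. HTO failure without instability converts to TKA (hardware
#' removal fee) and then follows the primary-TKA pathway. Death competes from
#' every state at the age-specific background rate.
NULL

.STATES <- c("WELL_PRIMARY", "FAIL_NO_INSTAB", "FAIL_INSTAB",
             "WELL_TKA_AFTER_HTO", "FAIL_AFTER_CONV_NO_INSTAB",
             "FAIL_AFTER_CONV_INSTAB", "WELL_POST_REV1",
             "FAIL_POST_REV1_NO_INSTAB", "FAIL_POST_REV1_INSTAB",
             "WELL_POST_VVC", "DEAD")

#' Build the state machine for one strategy
#'
#' @param strategy `"TKA"`, `"UKA"` or `"HTO"`.
#' @param params A [parameter_set()].
#' @return An object of class `strategy_model`: state table (utility,
#'   entry cost, transient flag), index surgery cost, and the age-independent
#'   conditional event matrix `Q` (transitions among the living).
#' @export
build_strategy_model <- function(strategy, params) {
  if (!strategy %in% c("TKA", "UKA", "HTO"))
    stop("unknown strategy: ", strategy, call. = FALSE)
  stopifnot(inherits(params, "parameter_set"))
  p <- lapply(params[param_registry()$name], `[[`, "mean")

  st <- data.frame(state = .STATES, utility = 0, entry_cost = 0,
                   transient = FALSE, stringsAsFactors = FALSE)
  rownames(st) <- .STATES
  set <- function(state, utility, entry_cost = 0, transient = FALSE) {
    st[state, c("utility", "entry_cost", "transient")] <<-
      list(utility, entry_cost, transient)
  }

  rev1_cost <- p$cost_rev_primary + p$fee_revTKA
  vvc_cost  <- p$cost_rev_vvc + p$fee_revTKA

  if (strategy == "TKA") {
    index_cost <- p$cost_TKA + p$fee_TKA
    set("WELL_PRIMARY", p$u_well_TKA)
    set("FAIL_NO_INSTAB", p$u_fail_TKA, rev1_cost, TRUE)
    fail_u <- p$u_fail_TKA
  } else if (strategy == "UKA") {
    index_cost <- p$cost_UKA + p$fee_UKA
    set("WELL_PRIMARY", p$u_well_UKA)
    set("FAIL_NO_INSTAB", p$u_fail_UKA, rev1_cost, TRUE)
    fail_u <- p$u_fail_UKA
  } else {
    index_cost <- p$cost_HTO + p$fee_HTO
    set("WELL_PRIMARY", p$u_well_HTO)
    # conversion to TKA with hardware removal, then the primary-TKA pathway
    set("FAIL_NO_INSTAB", p$u_fail_HTO, p$cost_TKA + p$fee_TKA_hw, TRUE)
    fail_u <- p$u_fail_TKA
  }
  # TKA-conversion chain states; only reachable from the HTO arm but defined
  # for every model so all transition rows are stochastic
  set("WELL_TKA_AFTER_HTO", p$u_tka_after_hto)
  set("FAIL_AFTER_CONV_NO_INSTAB", p$u_fail_TKA, rev1_cost, TRUE)
  set("FAIL_AFTER_CONV_INSTAB", p$u_fail_instab, vvc_cost, TRUE)
  instab_entry <- if (strategy == "HTO") p$cost_rev_vvc + p$fee_TKA_hw else vvc_cost
  set("FAIL_INSTAB", p$u_fail_instab, instab_entry, TRUE)
  set("WELL_POST_REV1", p$u_post_rev1)
  set("FAIL_POST_REV1_NO_INSTAB", fail_u, vvc_cost, TRUE)
  set("FAIL_POST_REV1_INSTAB", p$u_fail_instab, vvc_cost, TRUE)
  set("WELL_POST_VVC", p$u_post_vvc)
  set("DEAD", 0, 0, FALSE)

  n <- length(.STATES)
  Q <- matrix(0, n, n, dimnames = list(.STATES, .STATES))
  fail_split <- function(pf, fi) split_failure(pf, fi)

  if (strategy == "HTO") {
    sp <- fail_split(p$p_fail_HTO, p$f_instab_HTO)
  } else if (strategy == "UKA") {
    sp <- fail_split(p$p_fail_UKA, p$f_instab_UKA)
  } else {
    sp <- fail_split(p$p_fail_TKA, p$f_instab_TKA)
  }
  Q["WELL_PRIMARY", "FAIL_NO_INSTAB"] <- sp[["no_instab"]]
  Q["WELL_PRIMARY", "FAIL_INSTAB"] <- sp[["instab"]]
  Q["WELL_PRIMARY", "WELL_PRIMARY"] <- 1 - sum(sp)

  if (strategy == "HTO") {
    Q["FAIL_NO_INSTAB", "WELL_TKA_AFTER_HTO"] <- 1
  } else {
    Q["FAIL_NO_INSTAB", "WELL_POST_REV1"] <- 1
  }
  sp2 <- fail_split(p$p_fail_TKA, p$f_instab_TKA)
  Q["WELL_TKA_AFTER_HTO", "FAIL_AFTER_CONV_NO_INSTAB"] <- sp2[["no_instab"]]
  Q["WELL_TKA_AFTER_HTO", "FAIL_AFTER_CONV_INSTAB"] <- sp2[["instab"]]
  Q["WELL_TKA_AFTER_HTO", "WELL_TKA_AFTER_HTO"] <- 1 - sum(sp2)
  Q["FAIL_AFTER_CONV_NO_INSTAB", "WELL_POST_REV1"] <- 1
  Q["FAIL_AFTER_CONV_INSTAB", "WELL_POST_VVC"] <- 1
  Q["FAIL_INSTAB", "WELL_POST_VVC"] <- 1

  # post-revision chain reuses the primary-TKA failure parameters
  sp3 <- fail_split(p$p_fail_TKA, p$f_instab_TKA)
  Q["WELL_POST_REV1", "FAIL_POST_REV1_NO_INSTAB"] <- sp3[["no_instab"]]
  Q["WELL_POST_REV1", "FAIL_POST_REV1_INSTAB"] <- sp3[["instab"]]
  Q["WELL_POST_REV1", "WELL_POST_REV1"] <- 1 - sum(sp3)
  Q["FAIL_POST_REV1_NO_INSTAB", "WELL_POST_VVC"] <- 1
  Q["FAIL_POST_REV1_INSTAB", "WELL_POST_VVC"] <- 1
  Q["WELL_POST_VVC", "WELL_POST_VVC"] <- 1
  Q["DEAD", "DEAD"] <- 1

  reachable <- strategy_states(strategy)
  structure(list(strategy = strategy, states = st, Q = Q,
                 index_cost = index_cost, reachable = reachable),
            class = "strategy_model")
}

#' States reachable within a strategy's pathway
#'
#' @param strategy `"TKA"`, `"UKA"` or `"HTO"`.
#' @return Character vector of state names.
#' @export
strategy_states <- function(strategy) {
  conv <- c("WELL_TKA_AFTER_HTO", "FAIL_AFTER_CONV_NO_INSTAB",
            "FAIL_AFTER_CONV_INSTAB")
  if (strategy == "HTO") .STATES else setdiff(.STATES, conv)
}

#' @export
print.strategy_model <- function(x, ...) {
  cat(sprintf("<strategy_model> %s: index cost %.2f CAD, %d reachable states\n",
              x$strategy, x$index_cost, length(x$reachable)))
  invisible(x)
}

#' One row of the age-specific transition matrix
#'
#' Death is applied first at the age-specific background rate; the remaining
#' probability is distributed over the strategy's event transitions.
#' Transient (surgery) states route all survivors to their single successor.
#'
#' @param model A [build_strategy_model()] result.
#' @param state State name (alive).
#' @param age_months Age in months.
#' @param table A [life_table()].
#' @return Named probability vector over all states, summing to 1.
#' @export
transition_row <- function(model, state, age_months, table) {
  stopifnot(inherits(model, "strategy_model"))
  if (state == "DEAD") {
    row <- model$Q["DEAD", ]
    return(row)
  }
  m <- mortality_at(table, age_months)
  row <- (1 - m) * model$Q[state, ]
  row[["DEAD"]] <- row[["DEAD"]] + m
  row
}

# Full transition matrix at a given age: death first, events scaled by
# survival. Used by the engine (per year of age) and the microsimulation.
transition_matrix <- function(model, age_months, table) {
  m <- mortality_at(table, age_months)
  P <- (1 - m) * model$Q
  P[, "DEAD"] <- P[, "DEAD"] + m
  P["DEAD", ] <- 0
  P["DEAD", "DEAD"] <- 1
  P
}

#' Machine-readable structure dump
#'
#' Serialises states, utilities, entry costs and transition rules of one
#' strategy for audit or diffing.
#'
#' @param model A `strategy_model`.
#' @param path Optional path; when given, writes JSON and returns the path.
#' @return A list (or `path` invisibly when writing).
#' @export
structure_dump <- function(model, path = NULL) {
  stopifnot(inherits(model, "strategy_model"))
  live <- model$reachable
  dump <- list(
    strategy = model$strategy,
    index_cost = model$index_cost,
    states = model$states[model$states$state %in% live, ],
    transitions = {
      Q <- model$Q[live, live, drop = FALSE]
      idx <- which(Q > 0, arr.ind = TRUE)
      data.frame(from = rownames(Q)[idx[, 1]], to = colnames(Q)[idx[, 2]],
                 prob = Q[idx], stringsAsFactors = FALSE)
    })
  if (is.null(path)) return(dump)
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
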