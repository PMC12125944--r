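#' @name cli_reporting
#' @title Pipeline front ends
#'
#' @description
#' Stage functions tying the model into the full analysis pipeline. Each
#' takes a config path (or [parameter_set()]), a life-table CSV path (or
#' [life_table()]), writes its CSV/JSON artifacts into `out_dir`, and
#' records them in a JSON run manifest. A thin command-line wrapper over
#' these functions ships at `inst/cli/cua.R`
#' (`Rscript cua.R run --config table1.yaml --lifetable lt.csv --out res/`).
NULL

resolve_inputs <- function(config, lifetable) {
  params <- if (inherits(config, "parameter_set")) config
            else load_parameter_set(config)
  table <- if (inherits(lifetable, "life_table")) lifetable
           else read_life_table(lifetable)
  list(params = params, table = table,
       config_path = if (is.character(config)) config else NA_character_,
       lifetable_path = if (is.character(lifetable)) lifetable else NA_character_)
}

write_manifest <- function(out_dir, stage, inputs, seed, artifacts) {
  manifest <- list(
    stage = stage,
    config = inputs$config_path,
    config_md5 = if (!is.na(inputs$config_path))
      unname(tools::md5sum(inputs$config_path)) else NA_character_,
    lifetable = inputs$lifetable_path,
    lifetable_md5 = if (!is.na(inputs$lifetable_path))
      unname(tools::md5sum(inputs$lifetable_path)) else NA_character_,
    seed = seed,
    package_version = as.character(utils::packageVersion("kneecua")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    artifacts = basename(artifacts))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Base-case deterministic run
#'
#' Runs all three strategies deterministically, writes the league table,
#' per-strategy traces, survival/revision validation curves, and a manifest.
#'
#' @param config Config path or [parameter_set()].
#' @param lifetable Life-table CSV path or [life_table()].
#' @param out_dir Output directory (created if missing).
#' @param discount Optional discount-rate override.
#' @return The [league_table()], invisibly; artifacts on disk.
#' @export
cua_run <- function(config, lifetable, out_dir, discount = NULL) {
  inp <- resolve_inputs(config, lifetable)
  params <- inp$params
  if (!is.null(discount)) { params$annual_discount <- discount }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  runs <- list()
  for (s in c("TKA", "UKA", "HTO")) {
    model <- build_strategy_model(s, params)
    r <- run_cohort(model, inp$table, params)
    runs[[s]] <- r
    tp <- file.path(out_dir, paste0("trace_", s, ".csv"))
    write_trace(r, tp)
    cp <- file.path(out_dir, paste0("curves_", s, ".csv"))
    utils::write.csv(survival_and_revision_curves(r, model), cp,
                     row.names = FALSE)
    artifacts <- c(artifacts, tp, cp)
  }
  lt <- league_table(runs, wtp = params$wtp_per_qalm)
  lp <- file.path(out_dir, "league_table.csv")
  write_league_table(lt, lp)
  artifacts <- c(artifacts, lp)
  write_manifest(out_dir, "run", inp, seed = NA, artifacts = artifacts)
  message("base case: ",
          paste(sprintf("%s C=%.2f E=%.2f [%s]", lt$strategy, lt$cost,
                        lt$effect, lt$dominance), collapse = "; "))
  invisible(lt)
}

#' Probabilistic sensitivity analysis stage
#'
#' @inheritParams cua_run
#' @param iterations PSA iterations; `NULL` uses the config value.
#' @param seed RNG seed.
#' @param freeze Parameter names to freeze at base case, or `"all"`.
#' @return The [run_psa()] result, invisibly.
#' @export
cua_psa <- function(config, lifetable, out_dir, iterations = NULL,
                    seed = 42L, freeze = character()) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_psa(inp$params, inp$table, n = iterations, seed = seed,
                 freeze = freeze)
  pp <- file.path(out_dir, "psa_draws.csv")
  write_psa(res, pp)
  mp <- file.path(out_dir, "psa_means.csv")
  utils::write.csv(res$means, mp, row.names = FALSE)
  op <- file.path(out_dir, "psa_optimal.csv")
  probs <- optimal_probabilities(res, inp$params$wtp_per_qalm)
  utils::write.csv(data.frame(strategy = names(probs),
                              p_optimal = as.numeric(probs)),
                   op, row.names = FALSE)
  sc <- ice_scatter(res, "TKA", "UKA", wtp = inp$params$wtp_per_qalm)
  sp <- file.path(out_dir, "ice_scatter_UKA_vs_TKA.csv")
  utils::write.csv(sc$points, sp, row.names = FALSE)
  write_manifest(out_dir, "psa", inp, seed, c(pp, mp, op, sp))
  message(sprintf("PSA (%d iter): P(optimal) %s", res$n,
                  paste(sprintf("%s=%.3f", names(probs), probs),
                        collapse = " ")))
  invisible(res)
}

#' Cost-effectiveness acceptability curve stage
#'
#' @inheritParams cua_psa
#' @param wtp_grid WTP grid; defaults to [default_wtp_grid()].
#' @return The CEAC data.frame, invisibly.
#' @export
cua_ceac <- function(config, lifetable, out_dir, iterations = NULL,
                     seed = 42L, wtp_grid = default_wtp_grid()) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_psa(inp$params, inp$table, n = iterations, seed = seed)
  cv <- ceac(res, wtp_grid)
  cp <- file.path(out_dir, "ceac.csv")
  utils::write.csv(cv, cp, row.names = FALSE)
  dens <- nmb_density(res, wtp = inp$params$wtp_per_qalm)
  dp <- file.path(out_dir, "nmb_density.csv")
  long <- do.call(rbind, lapply(names(dens), function(s)
    cbind(strategy = s, dens[[s]])))
  utils::write.csv(long, dp, row.names = FALSE)
  write_manifest(out_dir, "ceac", inp, seed, c(cp, dp))
  invisible(cv)
}

#' Tornado stage
#'
#' @inheritParams cua_run
#' @param names Parameters to include; defaults to all with non-degenerate
#'   ranges.
#' @return The [tornado()] data.frame, invisibly.
#' @export
cua_tornado <- function(config, lifetable, out_dir, names = NULL) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tn <- tornado(inp$params, inp$table, names = names)
  tp <- file.path(out_dir, "tornado.csv")
  utils::write.csv(as.data.frame(tn), tp, row.names = FALSE)
  write_manifest(out_dir, "tornado", inp, NA, tp)
  message("tornado: most influential parameter is ", tn$parameter[1L])
  invisible(tn)
}

#' Two-way sensitivity stage
#'
#' @inheritParams cua_run
#' @param name_x,name_y Parameters to cross (defaults: the well-state
#'   utilities after TKA and UKA).
#' @param grid_size Grid points per axis.
#' @return The [two_way_map()] data.frame, invisibly.
#' @export
cua_twoway <- function(config, lifetable, out_dir, name_x = "u_well_TKA",
                       name_y = "u_well_UKA", grid_size = 21L) {
  inp <- resolve_inputs(config, lifetable)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rx <- dsa_range(inp$params, name_x, grid_size)
  ry <- dsa_range(inp$params, name_y, grid_size)
  mp <- two_way_map(inp$params, inp$table, name_x, name_y,
                    seq(rx$low, rx$high, length.out = rx$grid_size),
                    seq(ry$low, ry$high, length.out = ry$grid_size))
  tp <- file.path(out_dir, "two_way_map.csv")
  utils::write.csv(mp, tp, row.names = FALSE)
  write_manifest(out_dir, "twoway", inp, NA, tp)
  invisible(mp)
}

#' Sex-specific mortality scenario stage
#'
#' Re-runs the base case with a sex-specific life table; model structure and
#' all other inputs unchanged.
#'
#' @inheritParams cua_run
#' @param sex `"male"`, `"female"` or `"general"`.
#' @param lifetable Life-table CSV path or [life_table()] for that sex;
#'   `NULL` uses the bundled synthetic table.
#' @return The scenario [league_table()], invisibly.
#' @export
cua_scenario <- function(config, out_dir, sex = c("male", "female", "general"),
                         lifetable = NULL) {
  sex <- match.arg(sex)
  if (is.null(lifetable)) lifetable <- synthetic_life_table_path(sex)
  sub <- file.path(out_dir, paste0("scenario_", sex))
  cua_run(config, lifetable, sub)
}
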