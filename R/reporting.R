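#' Configuration for a multi-scenario run
#'
#' @param database path to a food database (directory of `foods.csv` +
#'   `requirements.csv`, or a `.json` file), or `NULL` to generate a
#'   synthetic database from `synthetic_seed`.
#' @param synthetic_seed seed for the generated database when `database` is
#'   `NULL`.
#' @param scenarios character vector of scenario ids to run (built-ins) or a
#'   list of [scenario()] objects.
#' @param uncertainty run the Monte Carlo engine per scenario.
#' @param n_iterations,mc_seed Monte Carlo size and seed (when `uncertainty`).
#' @param match_paper use the just-binding G1 budget cap (4.99 instead of
#'   5.00); see [builtin_scenario()].
#' @param output_dir directory for the report files; created if missing.
#' @param typical_diet include the typical-diet comparator (evaluated, not
#'   optimized, from [typical_energy_shares()]).
#' @return object of class `run_config`.
#' @export
run_config <- function(database = NULL, synthetic_seed = 1L,
                       scenarios = SCENARIO_IDS, uncertainty = FALSE,
                       n_iterations = 2000L, mc_seed = 1L,
                       match_paper = FALSE, output_dir = ".",
                       typical_diet = TRUE) {
  if (!length(scenarios)) stop("at least one scenario is required")
  structure(list(database = database, synthetic_seed = synthetic_seed,
                 scenarios = scenarios, uncertainty = uncertainty,
                 n_iterations = n_iterations, mc_seed = mc_seed,
                 match_paper = match_paper, output_dir = output_dir,
                 typical_diet = typical_diet),
            class = "run_config")
}

resolve_scenarios <- function(config) {
  lapply(config$scenarios, function(s) {
    if (inherits(s, "scenario")) s
    else builtin_scenario(s, match_paper = config$match_paper)
  })
}

resolve_database <- function(config) {
  if (is.null(config$database))
    generate_food_database(generator_config(seed = config$synthetic_seed))
  else if (dir.exists(config$database))
    load_food_database(config$database, "csv_pair")
  else
    load_food_database(config$database, "json")
}

fruit_veg_grams <- function(db, quantities) {
  fv <- has_tag(db, "fruit") | has_tag(db, "vegetable")
  sum(quantities[names(fv)[fv]], na.rm = TRUE)
}

#' Run a set of scenarios and write a report bundle
#'
#' Solves every scenario in the configuration on one database, optionally
#' runs the Monte Carlo engine per scenario, and writes:
#' `scenario_table.csv` (rows = cost/GHG/nutrient outputs, columns =
#' scenarios, with a row naming each scenario's objective),
#' `cost_ghg_points.csv` (one cost/GHG point per scenario plus the
#' typical-diet comparator), per-scenario simulation exports when
#' uncertainty is on, `summary.json` (the full machine-readable bundle every
#' table cell is recomputable from), and `run.log`.
#'
#' A scenario that fails to solve is recorded with its status and the run
#' continues; an error is raised only when every scenario fails.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the database, per-scenario solutions,
#'   simulation summaries (if any), the typical-diet evaluation and the
#'   paths written.
#' @export
run_scenarios <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  db <- resolve_database(config)
  scns <- resolve_scenarios(config)
  ids <- vapply(scns, `[[`, character(1), "id")

  sols <- list(); sims <- list(); status <- character(0)
  for (i in seq_along(scns)) {
    sol <- tryCatch(optimize_diet(db, scns[[i]]),
                    error = function(e) {
                      warning("scenario ", ids[i], " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    status[ids[i]] <- if (is.null(sol)) "error" else sol$status
    sols[[ids[i]]] <- sol
    if (config$uncertainty && !is.null(sol) && sol$status == "optimal") {
      sims[[ids[i]]] <- run_simulation(
        db, scns[[i]],
        uncertainty_spec(n_iterations = config$n_iterations,
                         seed = config$mc_seed))
      write_simulation(sims[[ids[i]]],
                       file.path(config$output_dir,
                                 paste0("simulation_", ids[i])))
    }
  }
  ok <- names(status)[status == "optimal"]
  if (!length(ok)) stop("all scenarios failed: ",
                        paste(ids, status, sep = "=", collapse = ", "))

  typical <- NULL
  if (config$typical_diet) {
    tq <- generate_typical_diet(db)
    typical <- evaluate_diet(db, tq)
  }

  # scenario table: rows = outputs, columns = scenarios
  nut_ids <- nutrient_ids(db)
  mk_col <- function(sol) {
    if (is.null(sol) || sol$status != "optimal")
      return(rep(NA_real_, 4 + length(nut_ids)))
    c(sol$objective_value, sol$cost, sol$ghg,
      fruit_veg_grams(db, sol$quantities), sol$nutrient_intakes[nut_ids])
  }
  tab <- vapply(sols, mk_col, numeric(4 + length(nut_ids)))
  rows <- c("objective_value", "cost_nzd", "ghg_kgco2e", "fruit_veg_g",
            paste0("nutrient_", nut_ids))
  scenario_table <- data.frame(output = rows, tab, check.names = FALSE)
  names(scenario_table) <- c("output", names(sols))
  obj_row <- data.frame(output = "objective",
                        t(vapply(sols, function(s)
                          if (is.null(s)) NA_character_ else s$objective,
                          character(1))), check.names = FALSE)
  names(obj_row) <- names(scenario_table)
  table_path <- file.path(config$output_dir, "scenario_table.csv")
  utils::write.csv(rbind(obj_row,
                         data.frame(lapply(scenario_table, as.character),
                                    check.names = FALSE)),
                   table_path, row.names = FALSE)

  pts <- data.frame(
    label = names(sols),
    cost_nzd = vapply(sols, function(s)
      if (is.null(s)) NA_real_ else s$cost, numeric(1)),
    ghg_kgco2e = vapply(sols, function(s)
      if (is.null(s)) NA_real_ else s$ghg, numeric(1)),
    kind = "optimized")
  if (!is.null(typical))
    pts <- rbind(pts, data.frame(label = "typical_diet",
                                 cost_nzd = typical$cost,
                                 ghg_kgco2e = typical$ghg,
                                 kind = "evaluated"))
  points_path <- file.path(config$output_dir, "cost_ghg_points.csv")
  utils::write.csv(pts, points_path, row.names = FALSE)

  summary_doc <- list(
    seed = if (is.null(config$database)) config$synthetic_seed else NA,
    database = if (is.null(config$database)) "synthetic" else config$database,
    n_foods = n_foods(db), status = as.list(status),
    scenarios = lapply(sols, function(s)
      if (is.null(s)) NULL else solution_as_doc(s)),
    typical_diet = if (is.null(typical)) NULL else solution_as_doc(typical),
    simulations = lapply(sims, function(s)
      list(summary = s$summary, ratios = s$ratios, n_feasible = s$n_feasible,
           n_infeasible = s$n_infeasible)))
  json_path <- file.path(config$output_dir, "summary.json")
  jsonlite::write_json(summary_doc, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")

  # hash the scientific configuration, not where it is written
  cfg_json <- jsonlite::toJSON(
    unclass(config)[setdiff(names(config), "output_dir")],
    auto_unbox = TRUE, force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  log_path <- file.path(config$output_dir, "run.log")
  writeLines(c(
    paste0("dietlp run"),
    paste0("config_md5: ", unname(tools::md5sum(tmp))),
    paste0("database: ", if (is.null(config$database)) paste0(
      "synthetic seed ", config$synthetic_seed) else config$database),
    paste0("uncertainty: ", config$uncertainty,
           if (config$uncertainty) paste0(" (n=", config$n_iterations,
                                          ", seed=", config$mc_seed, ")")),
    paste0("scenario status: ",
           paste(names(status), status, sep = "=", collapse = ", "))),
    log_path)
  unlink(tmp)

  invisible(list(db = db, solutions = sols, simulations = sims,
                 typical = typical, status = status,
                 paths = c(table = table_path, points = points_path,
                           summary = json_path, log = log_path)))
}
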