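#' Read the delimited input tables
#'
#' Small readers for the package's delimited-text interfaces: a medium
#' table (`id`, `concentration` in mM, optional `cost`), a cost table
#' (`id`, `cost`) and an uptake-rate table (`id`, `max_uptake` in
#' mmol gDW^-1 h^-1).
#'
#' @param path CSV file path.
#' @return a tibble with the documented columns.
#' @export
read_medium_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "concentration") %in% names(tab))) {
    stop("medium table must have columns id, concentration", call. = FALSE)
  }
  tab
}

#' @rdname read_medium_table
#' @export
read_cost_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "cost") %in% names(tab))) {
    stop("cost table must have columns id, cost", call. = FALSE)
  }
  tab
}

#' @rdname read_medium_table
#' @export
read_uptake_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("id", "max_uptake") %in% names(tab))) {
    stop("uptake table must have columns id, max_uptake", call. = FALSE)
  }
  tab
}

#' Run a named pipeline stage
#'
#' The command-line surface of the package: each subcommand reads its
#' inputs from a run configuration, executes the corresponding analysis and
#' writes machine-readable outputs (CSV/JSON) plus a `run.log` into the
#' output directory.
#'
#' Subcommands: `synth` (generate the synthetic model and tables, plus a
#' ready-to-use `run_config.json`), `augment` (add the IgG pathway to a
#' model file), `validate`, `scan`, `limiting`, `uncertainty`,
#' `medium-cost` and `medium-count`.
#'
#' @param name subcommand name.
#' @param config a named list (or path to a JSON file) with entries as
#'   produced by `synth`: `model`, `dialect`, `medium`, `costs`, `uptake`,
#'   `growth`, `free_exchanges`, `D`, `X`, `d_grid`, `x_grid`, `u_grid`,
#'   `fix_growth`, `eps_limiting`, `seed`, `out`, and for `augment` also
#'   `igg_stoich`/`id_map`.
#' @return invisibly, a list with `status` (0 on success) and the paths of
#'   the written artifacts. A solver infeasibility during `validate` is a
#'   reported finding, not a failure.
#' @export
run_subcommand <- function(name = c("synth", "augment", "validate", "scan",
                                    "limiting", "uncertainty",
                                    "medium-cost", "medium-count"),
                           config) {
  name <- match.arg(name)
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  out_dir <- config$out %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("stage: %s", name),
                 sprintf("time: %s", format(Sys.time())),
                 sprintf("solver: chemoflux dense two-phase simplex"),
                 sprintf("config_hash: %s", config_hash(config)))
  artifacts <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (name == "synth") {
    seed <- config$seed %||% 1L
    args <- config$toy %||% list()
    args$seed <- as.integer(seed)
    toy <- make_toy_network(do.call(toy_network_spec, args))
    write_synthetic_fixtures(toy, out_dir)
    cfg <- list(
      model = file.path(out_dir, "model.json"), dialect = "bigg-json",
      medium = file.path(out_dir, "medium.csv"),
      costs = file.path(out_dir, "costs.csv"),
      uptake = file.path(out_dir, "uptake.csv"),
      growth = file.path(out_dir, "growth.csv"),
      free_exchanges = toy$dataset$free_exchanges,
      D = toy$dataset$ground_truth$D_ref,
      X = toy$dataset$ground_truth$X_ref,
      seed = seed, out = out_dir)
    jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      toy$dataset$ground_truth, file.path(out_dir, "ground_truth.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    artifacts <- file.path(out_dir, c("model.json", "medium.csv",
                                      "costs.csv", "uptake.csv",
                                      "growth.csv", "run_config.json",
                                      "ground_truth.json"))
    note("wrote synthetic fixtures for seed %d", seed)
  } else if (name == "augment") {
    net <- load_model(config$model, config$dialect %||% "bigg-json")
    stoich <- read_igg_stoichiometry(config$igg_stoich)
    id_map <- read_id_mapping(config$id_map)
    net <- augment_with_igg(net, stoich, id_map)
    path <- file.path(out_dir, "model_igg.json")
    write_bigg_json(net, path)
    artifacts <- path
    note("augmented %s: %d metabolites, %d reactions", config$model,
         nrow(net$metabolites), nrow(net$reactions))
  } else {
    env <- load_stage_inputs(config)
    if (name == "validate") {
      res <- validate_against_dataset(env$net, env$spec, env$dataset)
      note("validation solve status: %s", res$status)
      path <- file.path(out_dir, "report.json")
      jsonlite::write_json(as.list(res), path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      artifacts <- path
    } else if (name == "scan") {
      hm <- scan_grid(env$net, env$spec$medium, env$dataset$uptake_bounds,
                      D_grid = config$d_grid %||% env$spec$D,
                      X_grid = config$x_grid %||% env$spec$X,
                      free_exchanges = env$dataset$free_exchanges)
      note("scan: %d cells, %d feasible", nrow(hm), sum(hm$feasible))
      path <- file.path(out_dir, "heatmap.csv")
      flat <- dplyr::mutate(
        hm, limiting = purrr::map_chr(.data$limiting, paste,
                                      collapse = "+"))
      readr::write_csv(flat, path)
      artifacts <- path
    } else if (name == "limiting") {
      base <- solve_problem(set_objective(build_problem(
        env$net, env$spec, env$dataset$uptake_bounds,
        free_exchanges = env$dataset$free_exchanges), "max_igg"))
      if (base$status != "optimal") {
        stop("baseline solve ", base$status, call. = FALSE)
      }
      fl <- find_limiting(env$net, env$spec, env$dataset$uptake_bounds,
                          igg_flux_fixed = base$objective_value,
                          eps = config$eps_limiting,
                          free_exchanges = env$dataset$free_exchanges)
      note("limiting nutrients: %s", paste(fl$limiting, collapse = ", "))
      path <- file.path(out_dir, "ranges.csv")
      readr::write_csv(fl$ranges, path)
      artifacts <- path
    } else if (name == "uncertainty") {
      us <- uncertainty_sweep(env$net, env$spec,
                              env$dataset$uptake_bounds,
                              u_grid = config$u_grid %||%
                                seq(0, 0.25, by = 0.05),
                              free_exchanges = env$dataset$free_exchanges)
      path <- file.path(out_dir, "uncertainty.csv")
      readr::write_csv(tibble::as_tibble(us), path)
      artifacts <- path
    } else if (name %in% c("medium-cost", "medium-count")) {
      base <- solve_problem(set_objective(build_problem(
        env$net, env$spec, env$dataset$uptake_bounds,
        free_exchanges = env$dataset$free_exchanges), "max_igg"))
      if (base$status != "optimal") {
        stop("baseline solve ", base$status, call. = FALSE)
      }
      om <- if (name == "medium-cost") {
        minimize_medium_cost(env$net, env$spec, env$dataset$uptake_bounds,
                             env$dataset$costs,
                             igg_flux_fixed = base$objective_value,
                             free_exchanges = env$dataset$free_exchanges)
      } else {
        minimize_total_inflow(env$net, env$spec,
                              env$dataset$uptake_bounds,
                              igg_flux_fixed = base$objective_value,
                              free_exchanges = env$dataset$free_exchanges)
      }
      note("production preserved at optimized medium: %s",
           attr(om, "production_preserved"))
      path <- file.path(out_dir, "optimized_medium.csv")
      readr::write_csv(tibble::as_tibble(om), path)
      artifacts <- path
      if (name == "medium-count") {
        cl <- classify_nutrients(env$net, env$spec,
                                 env$dataset$uptake_bounds,
                                 free_exchanges =
                                   env$dataset$free_exchanges)
        cpath <- file.path(out_dir, "classification.json")
        jsonlite::write_json(
          c(attr(cl, "sets"),
            list(baseline_production = attr(cl, "baseline_production"),
                 all_redundant_removed_ok =
                   attr(cl, "all_redundant_removed_ok"))),
          cpath, auto_unbox = FALSE, digits = NA, pretty = TRUE)
        artifacts <- c(artifacts, cpath)
      }
    }
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(status = 0L, artifacts = artifacts,
                 log = file.path(out_dir, "run.log")))
}

# Shared input loading for the analysis subcommands.
load_stage_inputs <- function(config) {
  for (f in c("model", "medium", "uptake")) {
    if (is.null(config[[f]])) {
      stop("usage error: config entry '", f, "' is required", call. = FALSE)
    }
    if (!file.exists(config[[f]])) {
      stop("usage error: file not found: ", config[[f]], call. = FALSE)
    }
  }
  net <- load_model(config$model, config$dialect %||% "bigg-json")
  med_tab <- read_medium_table(config$medium)
  costs <- if (!is.null(config$costs) && file.exists(config$costs)) {
    read_cost_table(config$costs)
  } else NULL
  medium <- medium_spec(med_tab, costs = costs)
  uptake <- read_uptake_table(config$uptake)
  growth <- if (!is.null(config$growth) && file.exists(config$growth)) {
    readr::read_csv(config$growth, show_col_types = FALSE)
  } else NULL
  dataset <- list(
    uptake_bounds = uptake,
    growth_rate = config$fix_growth %||% growth$growth_rate %||% NA,
    experimental_igg_flux = growth$experimental_igg_flux %||% NA_real_,
    costs = if (!is.null(costs)) stats::setNames(costs$cost, costs$id),
    free_exchanges = config$free_exchanges)
  spec <- chemostat_spec(D = config$D %||% stop("usage error: D required",
                                               call. = FALSE),
                         X = config$X,
                         cell_density = config$cell_density,
                         gdw_per_1e6cells = config$gdw_per_1e6cells %||%
                           3e-4,
                         medium = medium)
  list(net = net, spec = spec, dataset = dataset)
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  # small stable fingerprint; avoids a digest dependency
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)))
}
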