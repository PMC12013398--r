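#' Relative error between model and experiment
#'
#' `|model - experimental| / experimental`, the validation metric used to
#' compare predicted and measured antibody production fluxes.
#'
#' @param model model-predicted value.
#' @param experimental measured value; must be positive.
#' @return non-negative numeric.
#' @export
relative_error <- function(model, experimental) {
  if (any(experimental <= 0)) {
    stop("domain error: experimental value must be positive", call. = FALSE)
  }
  abs(model - experimental) / experimental
}

#' Validate the model against an uptake dataset
#'
#' Fixes the specific growth rate to the experimentally measured value,
#' bounds the uptake fluxes with the measured maximum uptake rates,
#' maximizes antibody secretion and reports the predicted flux together
#' with the relative error against the measured production.
#'
#' @param net an IgG-augmented [metabolic_network()].
#' @param spec a [chemostat_spec()].
#' @param dataset a list (or `synthetic_dataset`) with `uptake_bounds`,
#'   `growth_rate` (h^-1), `experimental_igg_flux` (mmol gDW^-1 h^-1) and
#'   optionally `free_exchanges`.
#' @return one-row tibble: `status`, `predicted_flux`, `experimental_flux`,
#'   `relative_error`, `growth_rate`. An infeasible fit is reported as such
#'   (`predicted_flux = NA`), never silently relaxed.
#' @export
validate_against_dataset <- function(net, spec, dataset) {
  prob <- build_problem(net, spec, dataset$uptake_bounds,
                        growth_fix = dataset$growth_rate,
                        free_exchanges = dataset$free_exchanges)
  sol <- solve_problem(set_objective(prob, "max_igg"))
  pred <- if (sol$status == "optimal") sol$objective_value else NA_real_
  tibble::tibble(
    status = sol$status,
    predicted_flux = pred,
    experimental_flux = dataset$experimental_igg_flux,
    relative_error = if (is.na(pred)) NA_real_ else
      relative_error(pred, dataset$experimental_igg_flux),
    growth_rate = dataset$growth_rate)
}

#' Production scan over dilution rate and biomass concentration
#'
#' For every grid cell `(D, X)` the growth rate is coupled to the dilution
#' rate (`mu = D`) and antibody secretion is maximized. Cells where the
#' coupled problem has no feasible solution (washout: `D` above the
#' attainable growth rate, or the medium cannot carry the biomass) are
#' marked infeasible and carry no limiting annotation.
#'
#' @param net an IgG-augmented [metabolic_network()].
#' @param medium a [medium_spec()].
#' @param uptake_bounds see [build_problem()].
#' @param D_grid dilution rates, h^-1.
#' @param X_grid biomass grid; gDW L^-1 when `X_units = "gdw"`, 10^6 cells
#'   mL^-1 when `X_units = "cells"` (converted with `gdw_per_1e6cells`).
#' @param X_units,gdw_per_1e6cells see [chemostat_spec()].
#' @param annotate_limiting if `TRUE`, each feasible cell is annotated with
#'   its limiting nutrients via [find_limiting()].
#' @param nutrients nutrient ids scanned for the limiting annotation;
#'   default all medium nutrients.
#' @param free_exchanges see [build_problem()].
#' @return an `igg_heatmap`: a tibble with one row per cell (`D`, `X`,
#'   `X_units`, `feasible`, `igg_flux` in mmol gDW^-1 h^-1,
#'   `igg_volumetric_rate` in uM h^-1, `limiting` list column of nutrient
#'   ids).
#' @export
scan_grid <- function(net, medium, uptake_bounds, D_grid, X_grid,
                      X_units = c("gdw", "cells"),
                      gdw_per_1e6cells = 3e-4,
                      annotate_limiting = TRUE, nutrients = NULL,
                      free_exchanges = NULL) {
  X_units <- match.arg(X_units)
  stopifnot(length(D_grid) > 0, length(X_grid) > 0,
            all(D_grid >= 0), all(X_grid > 0))
  grid <- tidyr::expand_grid(D = D_grid, X_raw = X_grid)
  cells <- purrr::pmap(grid, function(D, X_raw) {
    X <- if (X_units == "cells") {
      cells_to_biomass(X_raw, gdw_per_1e6cells)
    } else X_raw
    spec <- chemostat_spec(D = D, X = X, medium = medium)
    prob <- build_problem(net, spec, uptake_bounds,
                          free_exchanges = free_exchanges)
    sol <- solve_problem(set_objective(prob, "max_igg"))
    feas <- sol$status == "optimal"
    lim <- character(0)
    if (feas && annotate_limiting) {
      fl <- find_limiting(net, spec, uptake_bounds,
                          igg_flux_fixed = sol$objective_value,
                          nutrients = nutrients,
                          free_exchanges = free_exchanges)
      lim <- fl$limiting
    }
    tibble::tibble(
      D = D, X = X_raw, X_units = X_units, feasible = feas,
      igg_flux = if (feas) sol$objective_value else NA_real_,
      igg_volumetric_rate = if (feas) sol$igg_volumetric_rate else NA_real_,
      limiting = list(lim))
  })
  out <- dplyr::bind_rows(cells)
  class(out) <- c("igg_heatmap", class(out))
  out
}

#' Identify limiting metabolites by flux variability
#'
#' Implements the four-step limiting-metabolite criterion: (1) fix the
#' antibody secretion flux to its maximized value, (2) maximize and
#' minimize each nutrient's exchange flux one at a time, (3) compute the
#' flux range width, (4) a nutrient is limiting when the width is zero
#' (within `eps`): its exchange flux is pinned, so any perturbation of it
#' changes the attainable optimum.
#'
#' @inheritParams scan_grid
#' @param spec a [chemostat_spec()].
#' @param igg_flux_fixed the antibody secretion flux to hold, mmol gDW^-1
#'   h^-1 (the stage-1 maximum).
#' @param nutrients nutrient ids to test; default all medium nutrients.
#' @param eps range-width tolerance; default
#'   `1e-6 * max(1, |igg_flux_fixed|)` (an exact zero is numerically
#'   unattainable).
#' @return a `limiting_analysis` list: `limiting` (character vector of
#'   nutrient ids) and `ranges`, a tibble (`nutrient`, `reaction`,
#'   `min_flux`, `max_flux`, `width`, `limiting`) with every audited range.
#' @export
find_limiting <- function(net, spec, uptake_bounds, igg_flux_fixed,
                          nutrients = NULL, eps = NULL,
                          free_exchanges = NULL) {
  if (is.null(eps)) eps <- 1e-6 * max(1, abs(igg_flux_fixed))
  if (is.null(nutrients)) nutrients <- spec$medium$nutrients$id
  prob <- build_problem(net, spec, uptake_bounds,
                        free_exchanges = free_exchanges)
  prob <- fix_flux(prob, net$igg_exchange_id, igg_flux_fixed)
  rows <- purrr::map(nutrients, function(s) {
    rxn <- resolve_exchange(net, s)
    lo <- optimize_variable(prob, rxn, "min")
    hi <- optimize_variable(prob, rxn, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("inconsistency error: problem infeasible with IgG flux fixed ",
           "at ", igg_flux_fixed, call. = FALSE)
    }
    tibble::tibble(nutrient = s, reaction = rxn,
                   min_flux = lo$objective_value,
                   max_flux = hi$objective_value)
  })
  ranges <- dplyr::bind_rows(rows) |>
    dplyr::mutate(width = .data$max_flux - .data$min_flux,
                  limiting = .data$width <= eps)
  structure(list(limiting = ranges$nutrient[ranges$limiting],
                 ranges = ranges, eps = eps,
                 igg_flux_fixed = igg_flux_fixed),
            class = "limiting_analysis")
}

#' @export
print.limiting_analysis <- function(x, ...) {
  cat("<limiting_analysis> IgG flux fixed at ",
      format(x$igg_flux_fixed, digits = 6), "\n", sep = "")
  cat("  limiting: ",
      if (length(x$limiting)) paste(x$limiting, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Maximum production under medium uncertainty
#'
#' Lets every medium concentration range over `[c (1 - u), c (1 + u)]`
#' while the summed medium concentration is held at its nominal total, and
#' maximizes antibody secretion for each uncertainty degree `u`. Because
#' the feasible sets are nested in `u`, the production curve is
#' non-decreasing, and it saturates once the intervals exceed what the
#' kinetic uptake bounds can use.
#'
#' @inheritParams find_limiting
#' @param u_grid uncertainty fractions in `[0, 1)`.
#' @return an `uncertainty_curve` tibble: `u`, `status`, `igg_flux`,
#'   `igg_volumetric_rate`.
#' @export
uncertainty_sweep <- function(net, spec, uptake_bounds, u_grid,
                              free_exchanges = NULL) {
  stopifnot(all(u_grid >= 0), all(u_grid < 1))
  rows <- purrr::map(u_grid, function(u) {
    med <- spec$medium
    med$uncertainty <- u
    sp <- spec
    sp$medium <- med
    prob <- build_problem(net, sp, uptake_bounds,
                          medium_mode = "uncertain",
                          free_exchanges = free_exchanges)
    sol <- solve_problem(set_objective(prob, "max_igg"))
    tibble::tibble(
      u = u, status = sol$status,
      igg_flux = if (sol$status == "optimal") sol$objective_value
                 else NA_real_,
      igg_volumetric_rate = if (sol$status == "optimal")
        sol$igg_volumetric_rate else NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("uncertainty_curve", class(out))
  out
}

#' Cost-weighted medium minimization
#'
#' At a fixed antibody secretion flux, the nutrient inflows become decision
#' variables and the cost-weighted inflow sum `sum_s k_s lambda_in[s]` is
#' minimized. Optimized medium concentrations are recovered as
#' `lambda_in[s] / D`. The result is re-solved with the optimized medium
#' fixed to confirm the production level is preserved.
#'
#' @inheritParams find_limiting
#' @param costs named numeric (or tibble `id`, `cost`) of unit costs
#'   covering every medium nutrient.
#' @return an `optimized_medium`: a tibble (`nutrient`, `original_mM`,
#'   `optimized_mM`, `cost`) with attributes `total_cost`,
#'   `production_preserved`, `igg_flux_fixed`.
#' @export
minimize_medium_cost <- function(net, spec, uptake_bounds, costs,
                                 igg_flux_fixed, free_exchanges = NULL) {
  optimize_medium(net, spec, uptake_bounds, igg_flux_fixed,
                  weights = costs, free_exchanges = free_exchanges)
}

#' Nutrient-count (unweighted inflow) medium minimization
#'
#' Minimizes the unweighted inflow sum `sum_s lambda_in[s]` at fixed
#' antibody production; nutrients that are redundant for the fixed
#' phenotype end at zero inflow, so the optimized medium also has the
#' minimum number of nutrients.
#'
#' @inheritParams minimize_medium_cost
#' @return see [minimize_medium_cost()].
#' @export
minimize_total_inflow <- function(net, spec, uptake_bounds, igg_flux_fixed,
                                  free_exchanges = NULL) {
  optimize_medium(net, spec, uptake_bounds, igg_flux_fixed,
                  weights = NULL, free_exchanges = free_exchanges)
}

optimize_medium <- function(net, spec, uptake_bounds, igg_flux_fixed,
                            weights = NULL, free_exchanges = NULL) {
  prob <- build_problem(net, spec, uptake_bounds, medium_mode = "free",
                        free_exchanges = free_exchanges)
  prob <- fix_flux(prob, net$igg_exchange_id, igg_flux_fixed)
  if (is.null(weights)) {
    prob <- set_objective(prob, "min_total_inflow")
  } else {
    if (is.data.frame(weights)) {
      weights <- stats::setNames(weights$cost, weights$id)
    }
    prob <- set_objective(prob, "min_weighted_inflow", weights = weights)
  }
  sol <- solve_problem(prob)
  if (sol$status != "optimal") {
    stop("inconsistency error: medium optimization ", sol$status,
         " with IgG flux fixed at ", igg_flux_fixed, call. = FALSE)
  }
  D <- spec$medium   # placeholder to appease lints; real D below
  D <- prob$meta$D
  optimized_mM <- if (D > 0) sol$inflows / D else sol$inflows * NA_real_
  med <- spec$medium$nutrients
  out <- tibble::tibble(
    nutrient = prob$meta$nutrients,
    original_mM = med$concentration[match(prob$meta$nutrients, med$id)],
    optimized_mM = unname(optimized_mM[prob$meta$nutrients]),
    inflow = unname(sol$inflows[prob$meta$nutrients]),
    cost = if (is.null(weights)) NA_real_
           else unname(weights[prob$meta$nutrients]))
  total_cost <- if (is.null(weights)) NA_real_ else
    sum(out$inflow * out$cost)
  # confirm production is preserved at the optimized medium
  preserved <- FALSE
  if (D > 0) {
    med2 <- medium_spec(tibble::tibble(id = out$nutrient,
                                       concentration = out$optimized_mM))
    sp2 <- chemostat_spec(D = D, X = prob$meta$X, medium = med2)
    p2 <- build_problem(net, sp2, uptake_bounds,
                        free_exchanges = free_exchanges)
    s2 <- solve_problem(set_objective(p2, "max_igg"))
    preserved <- s2$status == "optimal" &&
      s2$objective_value >= igg_flux_fixed - 1e-9 * max(1, igg_flux_fixed)
  }
  structure(out, class = c("optimized_medium", class(out)),
            total_cost = total_cost, production_preserved = preserved,
            igg_flux_fixed = igg_flux_fixed,
            total_inflow = sum(out$inflow))
}

#' Classify medium nutrients by their effect on production
#'
#' For each nutrient the inflow from the reservoir is set to zero (the
#' nutrient is removed from the medium) while the dilution rate and biomass
#' concentration stay fixed, and antibody secretion is re-maximized.
#' Nutrients are *indispensable* when removal abolishes production (or
#' makes the operating point infeasible), *modulatory* when production is
#' reduced but not abolished, and *redundant* when production is unchanged
#' (relative change of at most `tol_change`). The three sets partition the
#' medium. Additionally, all redundant nutrients are removed simultaneously
#' and the check that baseline production survives is recorded.
#'
#' @inheritParams find_limiting
#' @param tol_change relative production change above which a nutrient
#'   counts as modulatory rather than redundant.
#' @param tol_zero production below `tol_zero * baseline` counts as null.
#' @return a `nutrient_classification`: tibble (`nutrient`, `production`,
#'   `relative_change`, `class`) with attributes `baseline_production`
#'   (uM h^-1, volumetric), `baseline_flux`, `all_redundant_removed_ok` and
#'   the three id sets as `sets`.
#' @export
classify_nutrients <- function(net, spec, uptake_bounds,
                               tol_change = 1e-6, tol_zero = 1e-6,
                               free_exchanges = NULL) {
  prob0 <- build_problem(net, spec, uptake_bounds,
                         free_exchanges = free_exchanges)
  base <- solve_problem(set_objective(prob0, "max_igg"))
  if (base$status != "optimal") {
    stop("baseline maximization ", base$status,
         "; cannot classify nutrients", call. = FALSE)
  }
  p0 <- base$objective_value
  nutrients <- prob0$meta$nutrients
  removed_production <- function(ids) {
    pr <- prob0
    for (s in ids) pr <- fix_flux(pr, paste0("lambda_in[", s, "]"), 0)
    sol <- solve_problem(pr)
    if (sol$status == "optimal") sol$objective_value else 0
  }
  prod <- vapply(nutrients, function(s) removed_production(s), numeric(1))
  rel_change <- if (p0 > 0) (p0 - prod) / p0 else rep(0, length(prod))
  cls <- dplyr::case_when(
    prod <= tol_zero * max(p0, 1e-12) ~ "indispensable",
    rel_change > tol_change ~ "modulatory",
    TRUE ~ "redundant")
  out <- tibble::tibble(nutrient = nutrients, production = prod,
                        relative_change = rel_change, class = cls)
  red <- out$nutrient[out$class == "redundant"]
  all_red_ok <- if (length(red) > 0) {
    abs(removed_production(red) - p0) <= tol_change * max(p0, 1e-12)
  } else TRUE
  structure(out, class = c("nutrient_classification", class(out)),
            baseline_flux = p0,
            baseline_production = base$igg_volumetric_rate,
            all_redundant_removed_ok = all_red_ok,
            sets = list(
              indispensable = out$nutrient[out$class == "indispensable"],
              modulatory = out$nutrient[out$class == "modulatory"],
              redundant = red))
}

#' @export
print.nutrient_classification <- function(x, ...) {
  s <- attr(x, "sets")
  cat("<nutrient_classification> baseline ",
      format(attr(x, "baseline_production"), digits = 6), " uM/h\n",
      sep = "")
  for (k in names(s)) {
    cat("  ", format(k, width = 13), ": ",
        if (length(s[[k]])) paste(s[[k]], collapse = ", ") else "(none)",
        "\n", sep = "")
  }
  cat("  all redundant removable together: ",
      attr(x, "all_redundant_removed_ok"), "\n", sep = "")
  invisible(x)
}
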