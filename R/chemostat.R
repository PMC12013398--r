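#' Medium specification
#'
#' Nominal nutrient concentrations of the feed medium, optional unit costs,
#' and the batch-to-batch uncertainty fraction used by
#' [uncertainty_sweep()].
#'
#' @param nutrients a tibble/data frame with columns `id`, `concentration`
#'   (mM), or a named numeric vector of concentrations.
#' @param costs optional named numeric vector or tibble (`id`, `cost`) of
#'   unit costs (cost per mmol); ids must be a subset of the nutrient ids.
#' @param uncertainty fraction `u` in `[0, 1)`: each concentration `c` may
#'   range over `[c (1 - u), c (1 + u)]` while the summed concentration is
#'   held at its nominal total.
#' @return an object of class `medium_spec`.
#' @export
medium_spec <- function(nutrients, costs = NULL, uncertainty = 0) {
  if (is.numeric(nutrients) && !is.null(names(nutrients))) {
    nutrients <- tibble::tibble(id = names(nutrients),
                                concentration = unname(nutrients))
  }
  nutrients <- tibble::as_tibble(nutrients)
  stopifnot(all(c("id", "concentration") %in% names(nutrients)))
  if (any(nutrients$concentration < 0)) {
    stop("medium concentrations must be >= 0", call. = FALSE)
  }
  if (anyDuplicated(nutrients$id)) {
    stop("duplicate nutrient ids in medium", call. = FALSE)
  }
  if (!is.null(costs)) {
    if (is.data.frame(costs)) {
      costs <- stats::setNames(costs$cost, costs$id)
    }
    extra <- setdiff(names(costs), nutrients$id)
    if (length(extra) > 0) {
      stop("cost map has ids outside the medium: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (uncertainty < 0 || uncertainty >= 1) {
    stop("uncertainty must lie in [0, 1)", call. = FALSE)
  }
  structure(list(nutrients = nutrients, costs = costs,
                 uncertainty = uncertainty),
            class = "medium_spec")
}

#' Chemostat operating point
#'
#' Fixes the macroscopic bioreactor variables: dilution rate `D` (h^-1),
#' biomass concentration `X` (gDW L^-1) and the feed medium. `X` may instead
#' be given as a viable cell density (10^6 cells mL^-1), converted with
#' `X = cell_density * gdw_per_1e6cells * 1000`, i.e. gDW per 10^6 cells
#' times cells per litre.
#'
#' @param D dilution rate, h^-1 (>= 0).
#' @param X biomass concentration, gDW L^-1 (>= 0); or `NULL` if
#'   `cell_density` is given.
#' @param medium a [medium_spec()].
#' @param cell_density optional cell density in 10^6 cells mL^-1.
#' @param gdw_per_1e6cells conversion constant, gDW per 10^6 cells. The
#'   default 3e-4 (about 300 pg dry weight per cell) is a documented
#'   placeholder typical of CHO cultures.
#' @return an object of class `chemostat_spec`.
#' @export
chemostat_spec <- function(D, X = NULL, medium, cell_density = NULL,
                           gdw_per_1e6cells = 3e-4) {
  if (D < 0) stop("domain error: D must be >= 0", call. = FALSE)
  if (is.null(X)) {
    if (is.null(cell_density)) {
      stop("either X or cell_density must be given", call. = FALSE)
    }
    X <- cells_to_biomass(cell_density, gdw_per_1e6cells)
  }
  if (X < 0) stop("domain error: X must be >= 0", call. = FALSE)
  stopifnot(inherits(medium, "medium_spec"))
  structure(list(D = D, X = X, medium = medium,
                 cell_density = cell_density,
                 gdw_per_1e6cells = gdw_per_1e6cells),
            class = "chemostat_spec")
}

#' @rdname chemostat_spec
#' @param cell_density cell density, 10^6 cells mL^-1.
#' @export
cells_to_biomass <- function(cell_density, gdw_per_1e6cells = 3e-4) {
  cell_density * gdw_per_1e6cells * 1000
}

#' Assemble the steady-state coupled problem
#'
#' Builds the linear program that couples the intracellular flux vector `v`
#' (one variable per reaction) to the chemostat mass balances at steady
#' state. Per medium nutrient `s` the balance `(s_m - s_t) D - u_s X = 0`
#' becomes the row `lambda_in[s] - D tank[s] + X v_ex(s) = 0` with
#' `lambda_in[s] = D s_m` (exchange fluxes are signed: uptake negative, so
#' `u_s = -v_ex(s)`). The biomass balance `(mu - D) X = 0` is imposed as the
#' row `mu = D` whenever `X > 0` (or `mu =` `growth_fix`), and the product
#' balance `u_a X - D a_t = 0` links antibody secretion to the tank.
#'
#' @param net an IgG-augmented [metabolic_network()].
#' @param spec a [chemostat_spec()].
#' @param uptake_bounds named numeric (or tibble `id`, `max_uptake`) of
#'   maximum uptake rates, mmol gDW^-1 h^-1, keyed by nutrient metabolite id
#'   or exchange reaction id. Applied to the uptake magnitude only; the
#'   secretion direction inherits the model bound.
#' @param growth_fix `NULL` to couple growth to the dilution rate
#'   (`mu = D`), a number to fix `mu` to an experimental growth rate, or
#'   `NA` to leave growth unconstrained (the pre-coupling regime in which
#'   the growth/production trade-off shows up).
#' @param medium_mode `"fixed"` (concentrations at their nominal values),
#'   `"uncertain"` (each in `[c(1-u), c(1+u)]` with the summed concentration
#'   fixed) or `"free"` (inflows become non-negative decision variables, used
#'   by the medium minimization analyses).
#' @param free_exchanges exchange reaction ids exempt from medium coupling
#'   (water, protons, secreted byproducts): they keep their model bounds.
#'   All other exchange reactions of metabolites absent from the medium have
#'   uptake blocked (lower bound clamped at 0), so the medium defines what
#'   the culture can consume.
#' @return an object of class `coupled_problem`.
#' @export
build_problem <- function(net, spec, uptake_bounds = NULL, growth_fix = NULL,
                          medium_mode = c("fixed", "uncertain", "free"),
                          free_exchanges = NULL) {
  stopifnot(inherits(net, "chemoflux_network"),
            inherits(spec, "chemostat_spec"))
  medium_mode <- match.arg(medium_mode)
  D <- spec$D
  X <- spec$X
  med <- spec$medium$nutrients
  nutrients <- med$id
  if (is.data.frame(uptake_bounds)) {
    uptake_bounds <- stats::setNames(uptake_bounds$max_uptake,
                                     uptake_bounds$id)
  }

  rxns <- net$reactions
  n_rxn <- nrow(rxns)
  ex_of <- vapply(nutrients, function(s) resolve_exchange(net, s),
                  character(1))
  if (!is.null(uptake_bounds)) {
    ub_ex <- vapply(names(uptake_bounds),
                    function(s) resolve_exchange(net, s), character(1))
  } else {
    ub_ex <- character(0)
  }

  lb <- rxns$lower_bound
  ub <- rxns$upper_bound
  names(lb) <- names(ub) <- rxns$id
  # uptake caps: bound the uptake magnitude of the mapped exchange reactions
  for (i in seq_along(ub_ex)) {
    r <- ub_ex[i]
    cap <- abs(uptake_bounds[[i]])
    lb[r] <- max(lb[r], -cap)
  }
  # exchanges not in the medium and not exempt: no uptake
  ex_ids <- rxns$id[rxns$is_exchange]
  closed <- setdiff(ex_ids, c(ex_of, free_exchanges,
                              net$igg_exchange_id))
  lb[closed] <- pmax(lb[closed], 0)

  n_s <- length(nutrients)
  var_names <- c(rxns$id,
                 paste0("lambda_in[", nutrients, "]"),
                 paste0("tank[", nutrients, "]"),
                 "tank[igg]")
  kind <- c(rep("flux", n_rxn), rep("inflow", n_s), rep("tank", n_s),
            "product_tank")
  idx_flux <- seq_len(n_rxn)
  idx_in <- n_rxn + seq_len(n_s)
  idx_tank <- n_rxn + n_s + seq_len(n_s)
  idx_at <- n_rxn + 2 * n_s + 1
  nv <- idx_at

  lbv <- c(unname(lb), numeric(n_s), numeric(n_s), 0)
  ubv <- c(unname(ub), numeric(n_s), rep(Inf, n_s), Inf)
  lam_nom <- D * med$concentration
  u <- spec$medium$uncertainty
  if (medium_mode == "fixed") {
    lbv[idx_in] <- lam_nom
    ubv[idx_in] <- lam_nom
  } else if (medium_mode == "uncertain") {
    lbv[idx_in] <- lam_nom * (1 - u)
    ubv[idx_in] <- lam_nom * (1 + u)
  } else {
    lbv[idx_in] <- 0
    ubv[idx_in] <- Inf
  }

  S <- stoich_matrix(net)
  n_m <- nrow(S)
  rows <- list()
  row_names <- character(0)
  row_kind <- character(0)
  rhs <- numeric(0)
  add_row <- function(coefs, name, kind, b) {
    r <- numeric(nv)
    r[coefs$i] <- coefs$x
    rows[[length(rows) + 1]] <<- r
    row_names <<- c(row_names, name)
    row_kind <<- c(row_kind, kind)
    rhs <<- c(rhs, b)
  }
  # intracellular mass balances S v = 0
  for (i in seq_len(n_m)) {
    nz <- which(S[i, ] != 0)
    add_row(list(i = nz, x = S[i, nz]),
            paste0("mass[", rownames(S)[i], "]"), "mass_balance", 0)
  }
  # nutrient balances lambda_in - D tank + X v_ex = 0
  for (k in seq_len(n_s)) {
    j <- match(ex_of[k], rxns$id)
    add_row(list(i = c(idx_in[k], idx_tank[k], j), x = c(1, -D, X)),
            paste0("nutrient[", nutrients[k], "]"), "nutrient_balance", 0)
  }
  # biomass row
  j_bio <- match(net$biomass_reaction_id, rxns$id)
  growth_mode <- if (is.null(growth_fix)) "couple"
                 else if (is.na(growth_fix)) "free" else "fix"
  if (growth_mode == "fix") {
    add_row(list(i = j_bio, x = 1), "biomass", "biomass", growth_fix)
  } else if (growth_mode == "couple" && X > 0) {
    add_row(list(i = j_bio, x = 1), "biomass", "biomass", D)
  }
  # antibody row u_a X - D a_t = 0
  if (!is.null(net$igg_exchange_id)) {
    j_igg <- match(net$igg_exchange_id, rxns$id)
    add_row(list(i = c(j_igg, idx_at), x = c(X, -D)),
            "antibody", "antibody", 0)
  }
  # total medium concentration, uncertain mode only
  if (medium_mode == "uncertain") {
    add_row(list(i = idx_in, x = rep(1, n_s)),
            "medium_total", "medium_total", sum(lam_nom))
  }

  A <- do.call(rbind, rows)
  colnames(A) <- var_names
  prob <- structure(
    list(A = A,
         rhs = rhs,
         rows = tibble::tibble(name = row_names, kind = row_kind, rhs = rhs),
         vars = tibble::tibble(name = var_names, kind = kind,
                               lb = lbv, ub = ubv),
         objective = list(sense = "max",
                          coef = stats::setNames(
                            as.numeric(var_names == net$igg_exchange_id %||%
                                         ""), var_names)),
         meta = list(D = D, X = X, nutrients = nutrients,
                     exchange_of = ex_of, medium = med,
                     costs = spec$medium$costs,
                     biomass_reaction_id = net$biomass_reaction_id,
                     igg_exchange_id = net$igg_exchange_id,
                     growth_mode = growth_mode, medium_mode = medium_mode,
                     idx = list(flux = idx_flux, inflow = idx_in,
                                tank = idx_tank, at = idx_at))),
    class = "coupled_problem")
  if (is.null(net$igg_exchange_id)) prob <- set_objective(prob, "max_growth")
  prob
}

#' @export
print.coupled_problem <- function(x, ...) {
  cat("<coupled_problem>\n")
  cat("  variables:  ", nrow(x$vars), " (",
      sum(x$vars$kind == "flux"), " fluxes, ",
      length(x$meta$nutrients), " nutrients)\n", sep = "")
  cat("  rows:       ", nrow(x$rows), "\n", sep = "")
  cat("  D = ", x$meta$D, " h^-1, X = ", x$meta$X, " gDW/L, growth mode: ",
      x$meta$growth_mode, "\n", sep = "")
  invisible(x)
}

#' Set the optimization objective of a coupled problem
#'
#' @param prob a [build_problem()] result.
#' @param target one of `"max_igg"` (maximize the antibody secretion flux),
#'   `"max_growth"`, `"min_weighted_inflow"` (minimize the cost-weighted sum
#'   of nutrient inflows) or `"min_total_inflow"` (unweighted sum).
#' @param weights named numeric of nutrient weights (cost per mmol), needed
#'   for `"min_weighted_inflow"`; ids keyed as in the medium.
#' @return `prob` with the objective replaced; constraints untouched.
#' @export
set_objective <- function(prob, target = c("max_igg", "max_growth",
                                           "min_weighted_inflow",
                                           "min_total_inflow"),
                          weights = NULL) {
  stopifnot(inherits(prob, "coupled_problem"))
  target <- match.arg(target)
  coef <- stats::setNames(numeric(nrow(prob$vars)), prob$vars$name)
  meta <- prob$meta
  if (target == "max_igg") {
    if (is.null(meta$igg_exchange_id)) {
      stop("network has no IgG exchange reaction", call. = FALSE)
    }
    coef[meta$igg_exchange_id] <- 1
    sense <- "max"
  } else if (target == "max_growth") {
    coef[meta$biomass_reaction_id] <- 1
    sense <- "max"
  } else {
    lam <- paste0("lambda_in[", meta$nutrients, "]")
    if (target == "min_weighted_inflow") {
      if (is.null(weights)) {
        stop("min_weighted_inflow requires weights", call. = FALSE)
      }
      if (is.data.frame(weights)) {
        weights <- stats::setNames(weights$cost, weights$id)
      }
      missing_w <- setdiff(meta$nutrients, names(weights))
      if (length(missing_w) > 0) {
        stop("mapping error: no weight for nutrients: ",
             paste(missing_w, collapse = ", "), call. = FALSE)
      }
      unknown <- setdiff(names(weights), meta$nutrients)
      if (length(unknown) > 0) {
        stop("mapping error: weights for unknown nutrients: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      coef[lam] <- unname(weights[meta$nutrients])
    } else {
      coef[lam] <- 1
    }
    sense <- "min"
  }
  prob$objective <- list(sense = sense, coef = coef)
  prob
}

#' Fix or re-bound a variable of a coupled problem
#'
#' `fix_flux()` pins a reaction flux (or any variable) to a value; used to
#' hold the IgG secretion flux at its stage-1 optimum for flux-variability
#' and medium-minimization analyses.
#'
#' @param prob a [build_problem()] result.
#' @param var variable name (reaction id, `lambda_in[s]`, ...).
#' @param value value to fix the variable at.
#' @param lb,ub new bounds for [set_var_bounds()].
#' @return `prob` with the bounds changed.
#' @export
fix_flux <- function(prob, var, value) {
  set_var_bounds(prob, var, value, value)
}

#' @rdname fix_flux
#' @export
set_var_bounds <- function(prob, var, lb, ub) {
  stopifnot(inherits(prob, "coupled_problem"))
  i <- match(var, prob$vars$name)
  if (is.na(i)) stop("unknown variable: ", var, call. = FALSE)
  prob$vars$lb[i] <- lb
  prob$vars$ub[i] <- ub
  prob
}

#' Solve a coupled steady-state problem
#'
#' @param prob a [build_problem()] result (with an objective from
#'   [set_objective()]).
#' @param tol feasibility tolerance for the steady-state rows, applied
#'   relative to each row's scale.
#' @return an object of class `chemoflux_solution`: `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, named `fluxes`
#'   (mmol gDW^-1 h^-1), `inflows` (mM h^-1), `tank_concentrations` (mM, the
#'   antibody tank concentration under id `igg`), `igg_volumetric_rate`
#'   (uM h^-1, `u_a X * 1000`) and `max_residual`. Flux fields are `NULL`
#'   unless the status is optimal.
#' @export
solve_problem <- function(prob, tol = 1e-9) {
  stopifnot(inherits(prob, "coupled_problem"))
  res <- solve_lp(unname(prob$objective$coef), prob$A, prob$rhs,
                  prob$vars$lb, prob$vars$ub,
                  sense = prob$objective$sense, tol = tol)
  out <- list(status = res$status, objective_value = res$objective,
              fluxes = NULL, inflows = NULL, tank_concentrations = NULL,
              igg_volumetric_rate = NULL, max_residual = NULL,
              meta = prob$meta)
  if (res$status == "optimal") {
    x <- stats::setNames(res$x, prob$vars$name)
    idx <- prob$meta$idx
    out$fluxes <- x[idx$flux]
    out$inflows <- stats::setNames(x[idx$inflow], prob$meta$nutrients)
    out$tank_concentrations <- c(
      stats::setNames(x[idx$tank], prob$meta$nutrients),
      igg = unname(x[idx$at]))
    resid <- as.vector(prob$A %*% res$x) - prob$rhs
    row_scale <- pmax(1, apply(abs(prob$A), 1, max))
    out$max_residual <- max(abs(resid) / row_scale)
    if (!is.null(prob$meta$igg_exchange_id)) {
      out$igg_volumetric_rate <-
        unname(x[prob$meta$igg_exchange_id]) * prob$meta$X * 1000
    }
  }
  structure(out, class = "chemoflux_solution")
}

#' @export
print.chemoflux_solution <- function(x, ...) {
  cat("<chemoflux_solution> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective: ", format(x$objective_value, digits = 6), "\n",
        sep = "")
    if (!is.null(x$igg_volumetric_rate)) {
      cat("  IgG volumetric rate: ",
          format(x$igg_volumetric_rate, digits = 6), " uM/h\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy a chemostat solution
#'
#' `tidy()` returns one row per model variable (fluxes, inflows, tank
#' concentrations); `glance()` returns a one-row summary.
#'
#' @param x a [solve_problem()] result.
#' @param ... unused.
#' @return a tibble.
#' @importFrom generics tidy
#' @exportS3Method generics::tidy
tidy.chemoflux_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble::tibble(variable = character(), kind = character(),
                          value = numeric()))
  }
  dplyr::bind_rows(
    tibble::tibble(variable = names(x$fluxes), kind = "flux",
                   value = unname(x$fluxes)),
    tibble::tibble(variable = names(x$inflows), kind = "inflow",
                   value = unname(x$inflows)),
    tibble::tibble(variable = names(x$tank_concentrations), kind = "tank",
                   value = unname(x$tank_concentrations)))
}

#' @rdname tidy.chemoflux_solution
#' @importFrom generics glance
#' @exportS3Method generics::glance
glance.chemoflux_solution <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    objective_value = x$objective_value,
    growth_rate = if (x$status == "optimal")
      unname(x$fluxes[x$meta$biomass_reaction_id]) else NA_real_,
    igg_flux = if (x$status == "optimal" && !is.null(x$meta$igg_exchange_id))
      unname(x$fluxes[x$meta$igg_exchange_id]) else NA_real_,
    igg_volumetric_rate = x$igg_volumetric_rate %||% NA_real_,
    max_residual = x$max_residual %||% NA_real_,
    D = x$meta$D, X = x$meta$X)
}

# Minimize/maximize one variable subject to the problem's constraints.
optimize_variable <- function(prob, var, sense) {
  coef <- stats::setNames(numeric(nrow(prob$vars)), prob$vars$name)
  coef[var] <- 1
  prob$objective <- list(sense = sense, coef = coef)
  solve_problem(prob)
}
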