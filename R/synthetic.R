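#' Specification for the synthetic toy network
#'
#' The generator emits a small, fully designed metabolic network plus the
#' matching medium/uptake/cost tables, so that every analysis stage of the
#' package runs without downloading a genome-scale model. The network is
#' built so that its biology is known by construction:
#'
#' * biomass and antibody production compete for every "indispensable"
#'   amino acid (both consume it; its uptake bound is set so that maximum
#'   growth equals `mu_max`),
#' * each indispensable nutrient is the sole source of a precursor required
#'   by both biomass and the antibody, so removing it abolishes production,
#' * each modulatory nutrient feeds a precursor that also has a
#'   capacity-capped internal bypass from glucose, so removing it reduces
#'   production to the bypass capacity without abolishing it,
#' * each redundant nutrient (and glucose) only feeds the energy pool, which
#'   is also replenished as a byproduct of precursor synthesis, so removing
#'   any or all of them leaves production unchanged,
#' * the first indispensable amino acid carries twice the antibody
#'   stoichiometry of the others, so at the reference operating point it is
#'   the unique limiting metabolite (its exchange-flux variability collapses
#'   to a point).
#'
#' Topology is deterministic given the counts; the seed only jitters medium
#' concentrations and nutrient costs.
#'
#' @param seed integer seed for the jitter.
#' @param n_indispensable,n_modulatory,n_redundant nutrient counts
#'   (`n_indispensable >= 1`, `n_modulatory >= 1`; glucose is always added
#'   and is redundant by design).
#' @param mu_max maximum achievable specific growth rate, h^-1.
#' @param uptake_cap maximum uptake rate of the non-growth-limiting
#'   nutrients, mmol gDW^-1 h^-1.
#' @param D_ref,X_ref reference chemostat operating point (h^-1, gDW L^-1)
#'   at which the designed optimum, limiting set and classification hold.
#' @param medium_margin ratio of the medium-supported uptake `D c / X` to
#'   the kinetic uptake cap. Values > 1 make the medium non-binding (the
#'   regime of the washout and classification analyses); values < 1 make the
#'   medium binding at the nominal composition, the regime in which medium
#'   uncertainty buys production until the kinetic caps saturate it.
#' @param modulatory_bypass_frac capacity of the internal bypass of each
#'   modulatory precursor, as a fraction of the reference antibody synthesis
#'   flux.
#' @return an object of class `toy_network_spec`.
#' @export
toy_network_spec <- function(seed = 1L, n_indispensable = 3,
                             n_modulatory = 2, n_redundant = 2,
                             mu_max = 0.03, uptake_cap = 0.03,
                             D_ref = 0.01, X_ref = 2,
                             medium_margin = 1.5,
                             modulatory_bypass_frac = 0.4) {
  stopifnot(n_indispensable >= 1, n_modulatory >= 1, n_redundant >= 0,
            mu_max > 0, uptake_cap > 0, D_ref >= 0, D_ref < mu_max,
            X_ref > 0, medium_margin > 0,
            modulatory_bypass_frac > 0, modulatory_bypass_frac < 1)
  structure(as.list(environment()), class = "toy_network_spec")
}

pick_names <- function(pool, n, prefix) {
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, sprintf("%s%02d", prefix, seq_len(n - length(pool))))
}

#' Generate the synthetic toy network and its dataset
#'
#' @param spec a [toy_network_spec()].
#' @return a list with elements `network` (an IgG-augmented
#'   [metabolic_network()]) and `dataset`, a `synthetic_dataset` list
#'   carrying `uptake_bounds`, `growth_rate`, `medium` (a [medium_spec()]
#'   with costs), `free_exchanges` and `ground_truth` (designed maximum
#'   growth rate, reference antibody optimum, limiting set and nutrient
#'   classification, all verified by direct solves at generation time).
#' @export
make_toy_network <- function(spec = toy_network_spec()) {
  stopifnot(inherits(spec, "toy_network_spec"))
  ind <- pick_names(c("lys", "his", "thr", "ile", "leu", "met", "phe",
                      "trp", "val"), spec$n_indispensable, "inda")
  mod <- pick_names(c("cys", "tyr"), spec$n_modulatory, "moda")
  red <- pick_names(c("gln", "ser", "asn", "asp", "pro", "arg", "glu"),
                    spec$n_redundant, "reda")
  nutrients <- c(ind, mod, red, "glc")
  met_id <- function(x) paste0(x, "_c")

  mets <- tibble::tibble(
    id = c(met_id(nutrients), met_id(paste0("q_", mod)),
           "e_c", "h2o_c", "h_c", "byp_c"),
    name = c(nutrients, paste0("precursor of ", mod),
             "energy equivalent", "water", "proton", "overflow byproduct"),
    compartment = "c")

  rx <- list()
  add_rx <- function(id, stoich, lb = 0, ub = 1000, exch = FALSE,
                     name = id) {
    rx[[length(rx) + 1]] <<- tibble::tibble(
      id = id, name = name, lower_bound = lb, upper_bound = ub,
      is_exchange = exch, stoich = list(stoich))
  }
  for (s in nutrients) {
    add_rx(paste0("EX_", met_id(s)), stats::setNames(-1, met_id(s)),
           lb = -1000, exch = TRUE)
  }
  for (s in c(ind, mod)) {     # overflow: excess amino acid degraded
    add_rx(paste0("DEG_", s),
           stats::setNames(c(-1, 1), c(met_id(s), "byp_c")))
  }
  add_rx("CAT_glc", c(glc_c = -1, e_c = 4))
  for (s in red) {             # catabolism of redundant amino acids
    add_rx(paste0("CAT_", s),
           stats::setNames(c(-1, 1), c(met_id(s), "e_c")))
  }
  add_rx("DEG_e", c(e_c = -1, byp_c = 1))
  p_ref <- (spec$mu_max - spec$D_ref) / 2  # reference subunit synthesis flux
  qb_cap <- spec$modulatory_bypass_frac * p_ref
  for (s in mod) {
    add_rx(paste0("QS_", s),
           stats::setNames(c(-1, 1, 2),
                           c(met_id(s), met_id(paste0("q_", s)), "e_c")))
    add_rx(paste0("QB_", s),
           stats::setNames(c(-1, 1), c("glc_c", met_id(paste0("q_", s)))),
           ub = qb_cap)
  }
  add_rx("BIOMASS_toy",
         stats::setNames(c(rep(-1, length(ind)), -0.5),
                         c(met_id(ind), "e_c")),
         name = "toy biomass")
  add_rx("EX_h2o_c", c(h2o_c = -1), lb = -1000, exch = TRUE)
  add_rx("EX_h_c", c(h_c = -1), exch = TRUE)
  add_rx("EX_byp_c", c(byp_c = -1), exch = TRUE)

  net <- metabolic_network(mets, dplyr::bind_rows(rx), "BIOMASS_toy",
                           id = sprintf("toy_gem_seed%d", spec$seed))

  # antibody pathway through the same augmentation machinery as real models;
  # the first indispensable amino acid carries coefficient 2
  aa_coeffs <- stats::setNames(
    c(2, rep(1, length(ind) - 1), rep(1, length(mod))),
    c(ind, paste0("Q", mod)))
  toy_map <- stats::setNames(
    c(met_id(ind), met_id(paste0("q_", mod)), "e_c", "h2o_c", "h_c"),
    c(ind, paste0("Q", mod), "GTP", "H2O", "H"))
  stoich <- igg_stoichiometry(aa_coeffs, gtp_coeff = 1, h2o_coeff = 1,
                              byproduct_coeffs = c(H = 1),
                              subunits_per_igg = 2)
  net <- augment_with_igg(net, stoich, toy_map)

  caps <- stats::setNames(
    c(rep(spec$mu_max, length(ind)),
      rep(spec$uptake_cap, length(mod) + length(red) + 1)),
    met_id(nutrients))
  conc_nom <- spec$medium_margin * caps * spec$X_ref / spec$D_ref
  jitter <- with_local_seed(spec$seed, stats::runif(length(nutrients),
                                                    0.95, 1.05))
  costs <- with_local_seed(spec$seed + 1, stats::setNames(
    c(stats::runif(length(ind), 1, 3),
      stats::runif(length(mod), 0.5, 1.5),
      stats::runif(length(red), 0.3, 1),
      0.05),
    met_id(nutrients)))
  medium <- medium_spec(
    tibble::tibble(id = met_id(nutrients),
                   concentration = unname(conc_nom * jitter)),
    costs = costs)

  igg_flux_ref <- p_ref / 2   # two subunits per IgG, non-binding medium
  dataset <- structure(list(
    uptake_bounds = tibble::tibble(id = names(caps),
                                   max_uptake = unname(caps)),
    growth_rate = spec$D_ref,
    experimental_igg_flux = 0.9 * (spec$mu_max - spec$D_ref) / 4,
    medium = medium,
    costs = costs,
    free_exchanges = c("EX_h2o_c", "EX_h_c", "EX_byp_c"),
    ground_truth = list(
      mu_max = spec$mu_max,
      igg_flux_ref = igg_flux_ref,
      igg_volumetric_ref = igg_flux_ref * spec$X_ref * 1000,
      limiting = met_id(ind[1]),
      classification = list(indispensable = met_id(ind),
                            modulatory = met_id(mod),
                            redundant = met_id(c(red, "glc"))),
      D_ref = spec$D_ref, X_ref = spec$X_ref),
    spec = spec), class = "synthetic_dataset")

  assert_ground_truth(net, dataset)
  # In a medium tight enough to bind (margin close to or below 1) the
  # reference optimum is medium-limited; record the solved value instead of
  # the closed form (the closed form is asserted in the generous regime).
  spec_ref <- chemostat_spec(D = spec$D_ref, X = spec$X_ref, medium = medium)
  pc <- build_problem(net, spec_ref, dataset$uptake_bounds,
                      free_exchanges = dataset$free_exchanges)
  sc <- solve_problem(set_objective(pc, "max_igg"))
  if (sc$status != "optimal") {
    stop("generation error: reference operating point infeasible",
         call. = FALSE)
  }
  if (spec$medium_margin * 0.95 >= 1.2 &&
      abs(sc$objective_value - igg_flux_ref) > 1e-8) {
    stop("generation error: designed reference optimum not realized",
         call. = FALSE)
  }
  dataset$ground_truth$igg_flux_ref <- sc$objective_value
  dataset$ground_truth$igg_volumetric_ref <- sc$igg_volumetric_rate
  list(network = net, dataset = dataset)
}

# run expr with a local RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Generation-time verification that the emitted network realizes the
# designed biology. Maximum growth and the growth/production dichotomy are
# kinetic-cap (cell-level) properties, so they are asserted under a
# deliberately generous medium that cannot bind before the uptake caps.
assert_ground_truth <- function(net, dataset) {
  gt <- dataset$ground_truth
  caps <- stats::setNames(dataset$uptake_bounds$max_uptake,
                          dataset$uptake_bounds$id)
  generous <- medium_spec(
    tibble::tibble(id = names(caps),
                   concentration = unname(10 * caps * gt$X_ref /
                                            max(gt$D_ref, 1e-6))),
    costs = dataset$costs)
  spec_ref <- chemostat_spec(D = gt$D_ref, X = gt$X_ref, medium = generous)
  # maximum growth with growth unconstrained
  pg <- build_problem(net, spec_ref, dataset$uptake_bounds, growth_fix = NA,
                      free_exchanges = dataset$free_exchanges)
  sg <- solve_problem(set_objective(pg, "max_growth"))
  if (sg$status != "optimal" ||
      abs(sg$objective_value - gt$mu_max) > 1e-8) {
    stop("generation error: designed mu_max not realized", call. = FALSE)
  }
  if (abs(sg$fluxes[[net$igg_exchange_id]]) > 1e-9) {
    stop("generation error: IgG flux not zero at maximum growth",
         call. = FALSE)
  }
  si <- solve_problem(set_objective(pg, "max_igg"))
  if (abs(si$fluxes[[net$biomass_reaction_id]]) > 1e-9) {
    stop("generation error: growth not zero at unconstrained IgG maximum",
         call. = FALSE)
  }
  # reference coupled optimum
  pc <- build_problem(net, spec_ref, dataset$uptake_bounds,
                      free_exchanges = dataset$free_exchanges)
  sc <- solve_problem(set_objective(pc, "max_igg"))
  if (sc$status != "optimal" ||
      abs(sc$objective_value - gt$igg_flux_ref) > 1e-8) {
    stop("generation error: designed reference optimum not realized",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a looser/stricter dataset pair
#'
#' Emulates a pair of uptake-rate datasets measured in two culture phases:
#' the second ("late exponential"-like) dataset has element-wise smaller
#' uptake bounds than the first ("high producer"-like), so at any operating
#' point its attainable antibody production is no larger.
#'
#' @param seed integer seed.
#' @param strict_factor multiplier (< 1) applied to the uptake bounds and
#'   growth rate of the stricter dataset.
#' @return list with `network`, `hp` and `late_exp` (both
#'   `synthetic_dataset`s sharing the network).
#' @export
make_dataset_pair <- function(seed = 1L, strict_factor = 0.6) {
  stopifnot(strict_factor > 0, strict_factor < 1)
  base <- make_toy_network(toy_network_spec(seed = seed))
  hp <- base$dataset
  late <- hp
  late$uptake_bounds$max_uptake <- hp$uptake_bounds$max_uptake *
    strict_factor
  late$growth_rate <- hp$growth_rate * strict_factor
  late$experimental_igg_flux <- hp$experimental_igg_flux * strict_factor
  gt <- late$ground_truth
  gt$mu_max <- gt$mu_max * strict_factor
  gt$D_ref <- gt$D_ref * strict_factor
  p_ref <- (gt$mu_max - gt$D_ref) / 2
  gt$igg_flux_ref <- NA_real_   # bypass caps are not rescaled; solved below
  late$ground_truth <- gt
  spec_ref <- chemostat_spec(D = gt$D_ref, X = gt$X_ref,
                             medium = late$medium)
  pc <- build_problem(base$network, spec_ref, late$uptake_bounds,
                      free_exchanges = late$free_exchanges)
  sc <- solve_problem(set_objective(pc, "max_igg"))
  if (sc$status != "optimal") {
    stop("generation error: strict dataset reference point infeasible",
         call. = FALSE)
  }
  late$ground_truth$igg_flux_ref <- sc$objective_value
  late$ground_truth$igg_volumetric_ref <- sc$igg_volumetric_rate
  list(network = base$network, hp = hp, late_exp = late)
}

#' Write the synthetic model and tables as plain-text fixtures
#'
#' Emits `model.json` (BiGG-dialect), `medium.csv` (`id`, `concentration`),
#' `costs.csv` (`id`, `cost`) and `uptake.csv` (`id`, `max_uptake`, plus the
#' growth rate as an attribute row in `growth.csv`) into `dir`.
#'
#' @param toy result of [make_toy_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixtures <- function(toy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bigg_json(toy$network, file.path(dir, "model.json"))
  ds <- toy$dataset
  readr::write_csv(ds$medium$nutrients, file.path(dir, "medium.csv"))
  readr::write_csv(tibble::tibble(id = names(ds$costs),
                                  cost = unname(ds$costs)),
                   file.path(dir, "costs.csv"))
  readr::write_csv(ds$uptake_bounds, file.path(dir, "uptake.csv"))
  readr::write_csv(tibble::tibble(growth_rate = ds$growth_rate,
                                  experimental_igg_flux =
                                    ds$experimental_igg_flux),
                   file.path(dir, "growth.csv"))
  invisible(dir)
}
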