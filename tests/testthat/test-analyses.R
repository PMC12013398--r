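# Bespoke two-route network: antibody synthesis consumes B only, growth
# consumes A only, and excess A can be overflow-degraded, so with a
# generous medium the uptake cap of B pins the antibody optimum (B is the
# limiting nutrient by construction) while A's exchange flux keeps slack.
tworoute_net <- function() {
  mets <- tibble::tibble(id = c("a_c", "b_c", "w_c", "igg_c"),
                         name = c("A", "B", "waste", "antibody"),
                         compartment = "c")
  rxns <- tibble::tibble(
    id = c("EX_a_c", "EX_b_c", "GROWTH", "SYNTH", "DEG_a", "EX_w_c",
           "EX_igg"),
    name = id,
    lower_bound = c(-10, -10, 0, 0, 0, 0, 0),
    upper_bound = 1000,
    is_exchange = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    stoich = list(c(a_c = -1), c(b_c = -1), c(a_c = -1),
                  c(b_c = -1, igg_c = 1), c(a_c = -1, w_c = 1),
                  c(w_c = -1), c(igg_c = -1)))
  metabolic_network(mets, rxns, "GROWTH", igg_exchange_id = "EX_igg",
                    id = "tworoute")
}

test_that("relative error reproduces the validation arithmetic", {
  expect_equal(relative_error(2.04e-5, 2.02e-5), 0.0099, tolerance = 1e-2)
  expect_equal(relative_error(5, 5), 0)
  expect_equal(relative_error(0, 5), 1)
  expect_equal(relative_error(3.205e-5, 2.44e-5), 0.3135, tolerance = 1e-4)
  expect_error(relative_error(1, 0), "domain error")
})

test_that("validation fixes growth to the measured rate and reports the error", {
  toy <- toy_fixture()
  ds <- toy$dataset
  res <- validate_against_dataset(toy$network, reference_spec(ds), ds)
  expect_equal(res$status, "optimal")
  expect_equal(res$predicted_flux, ds$ground_truth$igg_flux_ref,
               tolerance = 1e-9)
  # the synthetic "measured" production is 90% of the attainable optimum
  expect_equal(res$relative_error, 1 / 0.9 - 1, tolerance = 1e-9)
})

test_that("an unreachable growth rate is reported as infeasible, not relaxed", {
  toy <- toy_fixture()
  ds <- toy$dataset
  ds$growth_rate <- ds$ground_truth$mu_max * 2
  res <- validate_against_dataset(toy$network, reference_spec(ds), ds)
  expect_equal(res$status, "infeasible")
  expect_true(is.na(res$predicted_flux))
})

test_that("a binding uptake cap collapses the exchange-flux range of the limiting nutrient", {
  net <- tworoute_net()
  spec <- chemostat_spec(D = 0.01, X = 2,
                         medium = medium_spec(c(a_c = 50, b_c = 50)))
  caps <- c(a_c = 0.1, b_c = 0.1)
  base <- solve_problem(set_objective(
    build_problem(net, spec, caps), "max_igg"))
  expect_equal(base$objective_value, 0.1, tolerance = 1e-9)  # b cap binds
  fl <- find_limiting(net, spec, caps, base$objective_value,
                      nutrients = c("a_c", "b_c"))
  expect_identical(fl$limiting, "b_c")
  rg <- fl$ranges
  expect_equal(rg$width[rg$nutrient == "b_c"], 0, tolerance = 1e-9)
  expect_gt(rg$width[rg$nutrient == "a_c"], 1e-3)  # slack cap, not limiting

  # independent perturbation oracle: production responds only to the
  # limiting nutrient's cap
  bump <- function(caps2) {
    solve_problem(set_objective(build_problem(net, spec, caps2),
                                "max_igg"))$objective_value
  }
  expect_gt(bump(c(a_c = 0.1, b_c = 0.11)), base$objective_value + 1e-6)
  expect_equal(bump(c(a_c = 0.11, b_c = 0.1)), base$objective_value,
               tolerance = 1e-12)
})

test_that("classification recovers the designed nutrient structure and partitions the medium", {
  toy <- toy_fixture()
  ds <- toy$dataset
  gt <- ds$ground_truth$classification
  cl <- classify_nutrients(toy$network, reference_spec(ds),
                           ds$uptake_bounds,
                           free_exchanges = ds$free_exchanges)
  sets <- attr(cl, "sets")
  expect_setequal(sets$indispensable, gt$indispensable)
  expect_setequal(sets$modulatory, gt$modulatory)
  expect_setequal(sets$redundant, gt$redundant)
  # the three classes partition the medium
  expect_setequal(unlist(sets), ds$medium$nutrients$id)
  expect_equal(sum(lengths(sets)), nrow(ds$medium$nutrients))
  expect_true(attr(cl, "all_redundant_removed_ok"))
  # deterministic LP path: a rerun is identical
  cl2 <- classify_nutrients(toy$network, reference_spec(ds),
                            ds$uptake_bounds,
                            free_exchanges = ds$free_exchanges)
  expect_identical(tibble::as_tibble(cl), tibble::as_tibble(cl2))
})

test_that("a nutrient fed at zero concentration classifies as redundant", {
  toy <- toy_fixture(seed = 11)
  ds <- toy$dataset
  med <- ds$medium$nutrients
  med$concentration[med$id == "cys_c"] <- 0
  spec <- chemostat_spec(D = ds$ground_truth$D_ref,
                         X = ds$ground_truth$X_ref,
                         medium = medium_spec(med))
  cl <- classify_nutrients(toy$network, spec, ds$uptake_bounds,
                           free_exchanges = ds$free_exchanges)
  df <- tibble::as_tibble(cl)
  expect_equal(df$class[df$nutrient == "cys_c"], "redundant")
})

test_that("production under medium uncertainty starts at the baseline, rises, and saturates", {
  toy <- toy_fixture(seed = 13, medium_margin = 0.9)
  ds <- toy$dataset
  spec <- reference_spec(ds)
  base <- solve_problem(set_objective(
    build_problem(toy$network, spec, ds$uptake_bounds,
                  free_exchanges = ds$free_exchanges), "max_igg"))
  us <- uncertainty_sweep(toy$network, spec, ds$uptake_bounds,
                          u_grid = seq(0, 0.25, by = 0.05),
                          free_exchanges = ds$free_exchanges)
  expect_true(all(us$status == "optimal"))
  expect_equal(us$igg_flux[1], base$objective_value, tolerance = 1e-9)
  expect_true(all(diff(us$igg_flux) >= -1e-12))
  # kinetic caps saturate the curve well inside the swept range
  n <- nrow(us)
  expect_equal(us$igg_flux[n - 2], us$igg_flux[n], tolerance = 1e-9)
  expect_gt(us$igg_flux[n - 2], us$igg_flux[1] + 1e-6)
})

test_that("of two substitutable precursor sources only the cheaper is fed", {
  mets <- tibble::tibble(id = c("a_c", "b_c", "q_c", "igg_c"),
                         name = id, compartment = "c")
  rxns <- tibble::tibble(
    id = c("EX_a_c", "EX_b_c", "QA", "QB", "GROWTH", "SYNTH", "EX_igg"),
    name = id,
    lower_bound = c(-10, -10, 0, 0, 0, 0, 0),
    upper_bound = 1000,
    is_exchange = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stoich = list(c(a_c = -1), c(b_c = -1),
                  c(a_c = -1, q_c = 1), c(b_c = -1, q_c = 1),
                  c(q_c = -1), c(q_c = -1, igg_c = 1), c(igg_c = -1)))
  net <- metabolic_network(mets, rxns, "GROWTH",
                           igg_exchange_id = "EX_igg", id = "subst")
  spec <- chemostat_spec(D = 0.01, X = 2,
                         medium = medium_spec(c(a_c = 20, b_c = 20)))
  caps <- c(a_c = 0.1, b_c = 0.1)
  om <- minimize_medium_cost(net, spec, caps,
                             costs = c(a_c = 2, b_c = 1),
                             igg_flux_fixed = 0.02)
  df <- tibble::as_tibble(om)
  expect_equal(df$inflow[df$nutrient == "a_c"], 0, tolerance = 1e-10)
  expect_gt(df$inflow[df$nutrient == "b_c"], 0)
  expect_true(attr(om, "production_preserved"))
})

test_that("optimized media cost no more than the nominal medium and preserve production", {
  toy <- toy_fixture()
  ds <- toy$dataset
  spec <- reference_spec(ds)
  f <- ds$ground_truth$igg_flux_ref
  oc <- minimize_medium_cost(toy$network, spec, ds$uptake_bounds,
                             ds$costs, igg_flux_fixed = f,
                             free_exchanges = ds$free_exchanges)
  # the nominal medium attains the same production, so its cost bounds the
  # optimum from above
  nominal_cost <- sum(ds$costs[ds$medium$nutrients$id] *
                        spec$D * ds$medium$nutrients$concentration)
  expect_lte(attr(oc, "total_cost"), nominal_cost + 1e-9)
  expect_true(attr(oc, "production_preserved"))

  ot <- minimize_total_inflow(toy$network, spec, ds$uptake_bounds,
                              igg_flux_fixed = f,
                              free_exchanges = ds$free_exchanges)
  expect_true(attr(ot, "production_preserved"))
  # cost dominance: the cost-optimal medium is no dearer than the
  # count-optimal one priced with the same weights
  cost_of_ot <- sum(tibble::as_tibble(ot)$inflow *
                      ds$costs[tibble::as_tibble(ot)$nutrient])
  expect_lte(attr(oc, "total_cost"), cost_of_ot + 1e-9)
  # designed-redundant nutrients get zero inflow under Eq.-8-style
  # minimization
  dt <- tibble::as_tibble(ot)
  red <- ds$ground_truth$classification$redundant
  expect_true(all(abs(dt$inflow[dt$nutrient %in% red]) < 1e-10))
})

test_that("zero production with no maintenance demand needs no medium at all", {
  spec0 <- chemostat_spec(D = 0, X = 2,
                          medium = medium_spec(c(a_c = 5, b_c = 5)))
  ot <- minimize_total_inflow(micro_net(), spec0, micro_uptake(),
                              igg_flux_fixed = 0)
  expect_true(all(abs(tibble::as_tibble(ot)$inflow) < 1e-10))
})

test_that("a 1x1 production scan equals a single coupled solve", {
  toy <- toy_fixture()
  ds <- toy$dataset
  spec <- reference_spec(ds)
  hm <- scan_grid(toy$network, ds$medium, ds$uptake_bounds,
                  D_grid = spec$D, X_grid = spec$X,
                  free_exchanges = ds$free_exchanges)
  expect_equal(nrow(hm), 1)
  expect_true(hm$feasible)
  expect_equal(hm$igg_flux, ds$ground_truth$igg_flux_ref,
               tolerance = 1e-9)
  expect_identical(hm$limiting[[1]], ds$ground_truth$limiting)
})

test_that("washout cells are blank and carry no limiting annotation", {
  toy <- toy_fixture()
  ds <- toy$dataset
  mu_max <- ds$ground_truth$mu_max
  hm <- scan_grid(toy$network, ds$medium, ds$uptake_bounds,
                  D_grid = c(mu_max / 2, mu_max * 1.5),
                  X_grid = ds$ground_truth$X_ref,
                  free_exchanges = ds$free_exchanges)
  expect_equal(hm$feasible, c(TRUE, FALSE))
  expect_true(is.na(hm$igg_flux[2]))
  expect_length(hm$limiting[[2]], 0)
})
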