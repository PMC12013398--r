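test_that("the coupled problem has one balance row per metabolite, nutrient, biomass and product", {
  prob <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake())
  # 3 metabolites + 2 nutrients + 1 biomass + 1 antibody
  expect_equal(nrow(prob$rows), 3 + 2 + 1 + 1)
  expect_equal(sum(prob$rows$kind == "mass_balance"), 3)
  expect_equal(sum(prob$rows$kind == "nutrient_balance"), 2)
  expect_equal(sum(prob$rows$kind == "biomass"), 1)
  expect_equal(sum(prob$rows$kind == "antibody"), 1)
  # variables: fluxes + inflow/tank per nutrient + product tank
  expect_equal(nrow(prob$vars), 5 + 2 + 2 + 1)
})

test_that("nutrient inflow is the dilution rate times the medium concentration", {
  prob <- build_problem(micro_net(), micro_spec(D = 0.01),
                        uptake_bounds = micro_uptake())
  i <- match("lambda_in[a_c]", prob$vars$name)
  expect_equal(prob$vars$lb[i], 0.01 * 5)   # D * s_m = 0.05 mM/h
  expect_equal(prob$vars$ub[i], 0.01 * 5)
})

test_that("at X = 0 the biomass balance degenerates and growth is medium-free", {
  spec0 <- chemostat_spec(D = 0.01, X = 0,
                          medium = medium_spec(c(a_c = 5, b_c = 5)))
  prob <- build_problem(micro_net(), spec0)
  expect_equal(sum(prob$rows$kind == "biomass"), 0)
  # uptake is then limited only by the reaction bounds (-10 each)
  sol <- solve_problem(set_objective(prob, "max_growth"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})

test_that("the micro-network IgG optimum equals the hand-derived solution", {
  # D = 0.01, X = 2, c = 5 mM: the tank can deliver D c / X = 0.025
  # mmol/gDW/h of each nutrient; growth (mu = D) uses 0.01 of each, leaving
  # antibody synthesis at 0.015, i.e. 30 uM/h volumetric.
  prob <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake())
  sol <- solve_problem(set_objective(prob, "max_igg"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0.015, tolerance = 1e-9)
  expect_equal(sol$igg_volumetric_rate, 30, tolerance = 1e-7)
  expect_equal(unname(sol$fluxes["GROWTH"]), 0.01, tolerance = 1e-9)
})

test_that("steady-state coupling conservation holds at any optimum", {
  for (target in c("max_igg", "max_growth")) {
    prob <- build_problem(micro_net(), micro_spec(),
                          uptake_bounds = micro_uptake())
    sol <- solve_problem(set_objective(prob, target))
    expect_equal(sol$status, "optimal")
    D <- sol$meta$D
    X <- sol$meta$X
    for (s in sol$meta$nutrients) {
      v_ex <- sol$fluxes[[sol$meta$exchange_of[[s]]]]
      expect_lt(abs(sol$inflows[[s]] - D * sol$tank_concentrations[[s]] +
                      X * v_ex), 1e-9)
    }
    expect_lt(sol$max_residual, 1e-9)
  }
})

test_that("with growth left free the medium is spent on either growth or antibody", {
  prob <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake(), growth_fix = NA)
  igg <- solve_problem(set_objective(prob, "max_igg"))
  expect_equal(igg$objective_value, 0.025, tolerance = 1e-9)
  expect_equal(unname(igg$fluxes["GROWTH"]), 0, tolerance = 1e-9)
  gro <- solve_problem(set_objective(prob, "max_growth"))
  expect_equal(gro$objective_value, 0.025, tolerance = 1e-9)
  expect_equal(unname(gro$fluxes["EX_igg"]), 0, tolerance = 1e-9)
})

test_that("zero uptake bounds force zero production", {
  # growth left free: with nothing consumable the cell can neither grow
  # nor secrete (with growth coupled to D > 0 the same point is infeasible,
  # which solve reports faithfully)
  prob <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake(0), growth_fix = NA)
  sol <- solve_problem(set_objective(prob, "max_igg"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0, tolerance = 1e-12)
  coupled <- build_problem(micro_net(), micro_spec(),
                           uptake_bounds = micro_uptake(0))
  expect_equal(solve_problem(set_objective(coupled, "max_igg"))$status,
               "infeasible")
})

test_that("enlarging an uptake bound never decreases the IgG optimum", {
  vals <- c(0.01, 0.03, 0.05, 0.1, 0.5)
  prev <- -Inf
  for (cap in vals) {
    prob <- build_problem(micro_net(), micro_spec(),
                          uptake_bounds = c(a_c = cap, b_c = 0.1))
    sol <- solve_problem(set_objective(prob, "max_igg"))
    expect_gte(sol$objective_value, prev - 1e-12)
    prev <- sol$objective_value
  }
})

test_that("coupled optima match brute-force vertex enumeration", {
  prob <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake())
  for (target in c("max_igg", "max_growth")) {
    p <- set_objective(prob, target)
    expect_equal(solve_problem(p)$objective_value,
                 brute_solve_problem(p)$objective,
                 tolerance = 1e-8)
  }
  pf <- build_problem(micro_net(), micro_spec(),
                      uptake_bounds = micro_uptake(),
                      medium_mode = "free")
  pf <- fix_flux(pf, "EX_igg", 0.01)
  pf <- set_objective(pf, "min_total_inflow")
  expect_equal(solve_problem(pf)$objective_value,
               brute_solve_problem(pf)$objective, tolerance = 1e-8)
})

test_that("equal cost weights make the weighted and unweighted inflow objectives collinear", {
  base <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake(),
                        medium_mode = "free")
  base <- fix_flux(base, "EX_igg", 0.01)
  w <- 2.5
  pw <- set_objective(base, "min_weighted_inflow",
                      weights = c(a_c = w, b_c = w))
  pt <- set_objective(base, "min_total_inflow")
  sw <- solve_problem(pw)
  st <- solve_problem(pt)
  expect_equal(sw$objective_value, w * st$objective_value,
               tolerance = 1e-9)
})

test_that("domain and mapping errors are raised before solving", {
  expect_error(chemostat_spec(D = -0.01, X = 1,
                              medium = medium_spec(c(a_c = 1))),
               "domain error")
  expect_error(build_problem(micro_net(), micro_spec(),
                             uptake_bounds = c(nope_c = 0.1)),
               "mapping error")
  prob <- build_problem(micro_net(), micro_spec())
  expect_error(set_objective(prob, "min_weighted_inflow",
                             weights = c(a_c = 1, ghost_c = 1)),
               "mapping error")
  expect_error(set_objective(prob, "min_weighted_inflow",
                             weights = c(a_c = 1)),
               "mapping error")
})

test_that("cell density converts to biomass concentration as documented", {
  expect_equal(cells_to_biomass(10.624, gdw_per_1e6cells = 3e-4),
               10.624 * 0.3)
  spec <- chemostat_spec(D = 0.01, cell_density = 5,
                         medium = medium_spec(c(a_c = 1)))
  expect_equal(spec$X, 1.5)
})

test_that("tidy and glance expose the solution as tibbles", {
  prob <- build_problem(micro_net(), micro_spec(),
                        uptake_bounds = micro_uptake())
  sol <- solve_problem(set_objective(prob, "max_igg"))
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$kind), c("flux", "inflow", "tank"))
  expect_equal(nrow(td), 5 + 2 + 3)
  gl <- glance(sol)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$igg_flux, 0.015, tolerance = 1e-9)
  expect_equal(gl$growth_rate, 0.01, tolerance = 1e-9)
})
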