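test_that("a hand-written BiGG JSON fixture loads as written", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "id": "mini",
    "metabolites": [
      {"id": "a_c", "name": "A", "compartment": "c"},
      {"id": "b_c", "name": "B", "compartment": "c"}
    ],
    "reactions": [
      {"id": "BIOMASS_mini", "name": "growth",
       "metabolites": {"a_c": -1, "b_c": -0.5},
       "lower_bound": 0, "upper_bound": 1000,
       "objective_coefficient": 1}
    ],
    "genes": []
  }', path)
  net <- load_model(path, "bigg-json")
  expect_s3_class(net, "chemoflux_network")
  expect_equal(nrow(net$metabolites), 2)
  expect_equal(nrow(net$reactions), 1)
  expect_equal(net$biomass_reaction_id, "BIOMASS_mini")
  expect_equal(net$reactions$stoich[[1]][["b_c"]], -0.5)
})

test_that("malformed and structurally broken model files raise format errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "x", "metabolites": [{"id": "a_c"', bad)
  expect_error(read_bigg_json(bad), "format error")

  dangling <- withr::local_tempfile(fileext = ".json")
  writeLines('{
    "metabolites": [{"id": "a_c", "compartment": "c"}],
    "reactions": [{"id": "BIOMASS", "metabolites": {"ghost_c": -1},
                   "lower_bound": 0, "upper_bound": 10}]
  }', dangling)
  expect_error(read_bigg_json(dangling), "integrity error.*ghost_c")
})

test_that("write/load round trip reproduces ids, stoichiometries and bounds", {
  toy <- toy_fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_bigg_json(toy$network, path)
  back <- read_bigg_json(path)
  expect_identical(back$metabolites$id, toy$network$metabolites$id)
  expect_identical(back$reactions$id, toy$network$reactions$id)
  expect_equal(back$reactions$lower_bound, toy$network$reactions$lower_bound)
  expect_equal(back$reactions$upper_bound, toy$network$reactions$upper_bound)
  for (j in seq_len(nrow(back$reactions))) {
    a <- toy$network$reactions$stoich[[j]]
    b <- back$reactions$stoich[[j]]
    expect_identical(sort(names(a)), sort(names(b)))
    expect_equal(a[sort(names(a))], b[sort(names(a))])
  }
  expect_identical(back$biomass_reaction_id,
                   toy$network$biomass_reaction_id)
  expect_identical(back$igg_exchange_id, toy$network$igg_exchange_id)
})

test_that("SBML L3 FBC models load with bounds resolved from parameters", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini_sbml">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_a_c" compartment="c" name="A"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
      <species id="M_b_c" compartment="c" name="B"
               hasOnlySubstanceUnits="false" boundaryCondition="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_m10" value="-10" constant="true"/>
      <parameter id="ub_20" value="20" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="R_EX_a" reversible="true" fast="false"
                fbc:lowerFluxBound="lb_m10" fbc:upperFluxBound="ub_20">
        <listOfReactants>
          <speciesReference species="M_a_c" stoichiometry="1"
                            constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_BIOMASS" reversible="false" fast="false">
        <listOfReactants>
          <speciesReference species="M_a_c" stoichiometry="2"
                            constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_b_c" stoichiometry="1"
                            constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  net <- load_model(path, "sbml")
  expect_equal(nrow(net$metabolites), 2)
  expect_equal(nrow(net$reactions), 2)
  r_ex <- net$reactions[net$reactions$id == "R_EX_a", ]
  expect_equal(r_ex$lower_bound, -10)
  expect_equal(r_ex$upper_bound, 20)
  expect_true(r_ex$is_exchange)
  expect_equal(net$biomass_reaction_id, "R_BIOMASS")
  expect_equal(net$reactions$stoich[[2]],
               c(M_a_c = -2, M_b_c = 1))
})

test_that("validate_network reports findings as data, not errors", {
  net <- micro_net()
  expect_identical(nrow(validate_network(net)), 0L)

  broken <- net
  broken$reactions$lower_bound[3] <- 5
  broken$reactions$upper_bound[3] <- 1
  rep1 <- validate_network(broken)
  expect_equal(rep1$finding, "bound_violation")
  expect_equal(rep1$id, "GROWTH")

  arity <- net
  arity$reactions$stoich[[1]] <- c(a_c = -1, b_c = -1)  # degenerate exchange
  rep2 <- validate_network(arity)
  expect_true("exchange_arity" %in% rep2$finding)
  expect_equal(rep2$id[rep2$finding == "exchange_arity"], "EX_a_c")
})

test_that("constructor enforces uniqueness and resolvable references", {
  net <- micro_net()
  expect_error(
    metabolic_network(net$metabolites, net$reactions, "NOPE"),
    "biomass")
  dup <- dplyr::bind_rows(net$metabolites, net$metabolites[1, ])
  expect_error(metabolic_network(dup, net$reactions, "GROWTH"),
               "duplicate")
})

test_that("stoichiometric matrix has one row per metabolite, one column per reaction", {
  net <- micro_net()
  S <- stoich_matrix(net)
  expect_equal(dim(S), c(3, 5))
  expect_equal(S["a_c", "SYNTH"], -1)
  expect_equal(S["igg_c", "EX_igg"], -1)
  expect_equal(sum(S[, "EX_b_c"] != 0), 1)
})
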