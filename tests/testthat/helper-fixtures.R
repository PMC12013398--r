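# Hand-built micro network: two medium nutrients feeding competing biomass
# and antibody synthesis, small enough for hand/vertex-enumeration LP
# solutions. 3 metabolites, 5 reactions, 2 nutrients.
micro_net <- function() {
  mets <- tibble::tibble(
    id = c("a_c", "b_c", "igg_c"),
    name = c("nutrient A", "nutrient B", "antibody"),
    compartment = "c")
  rxns <- tibble::tibble(
    id = c("EX_a_c", "EX_b_c", "GROWTH", "SYNTH", "EX_igg"),
    name = c("A exchange", "B exchange", "biomass", "antibody synthesis",
             "antibody secretion"),
    lower_bound = c(-10, -10, 0, 0, 0),
    upper_bound = c(1000, 1000, 1000, 1000, 1000),
    is_exchange = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    stoich = list(c(a_c = -1), c(b_c = -1),
                  c(a_c = -1, b_c = -1),
                  c(a_c = -1, b_c = -1, igg_c = 1),
                  c(igg_c = -1)))
  metabolic_network(mets, rxns, "GROWTH", igg_exchange_id = "EX_igg",
                    id = "micro")
}

micro_spec <- function(D = 0.01, X = 2, conc = c(a_c = 5, b_c = 5)) {
  chemostat_spec(D = D, X = X, medium = medium_spec(conc))
}

micro_uptake <- function(cap = 0.1) c(a_c = cap, b_c = cap)

# Default toy fixture shared across tests (generation is fast but not free).
toy_fixture <- local({
  cache <- NULL
  function(seed = 1, ...) {
    args <- list(...)
    if (length(args) == 0 && seed == 1) {
      if (is.null(cache)) cache <<- make_toy_network(toy_network_spec(1))
      cache
    } else {
      make_toy_network(do.call(toy_network_spec, c(list(seed = seed), args)))
    }
  }
})

reference_spec <- function(dataset) {
  gt <- dataset$ground_truth
  chemostat_spec(D = gt$D_ref, X = gt$X_ref, medium = dataset$medium)
}
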