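#' Construct a metabolic network
#'
#' A `chemoflux_network` is the package's container for a constraint-based
#' (stoichiometric) model: a tibble of metabolites, a tibble of reactions with
#' signed stoichiometries and flux bounds, the id of the biomass reaction
#' (whose flux equals the specific growth rate \eqn{\mu}) and, after IgG
#' augmentation, the id of the antibody secretion reaction.
#'
#' @param metabolites tibble/data frame with columns `id`, `name`,
#'   `compartment`. Ids must be unique and non-empty; the compartment tag
#'   (e.g. `c`, `m`, `r`, `e`) must be non-empty.
#' @param reactions tibble/data frame with columns `id`, `name`,
#'   `lower_bound`, `upper_bound` (mmol gDW\eqn{^{-1}} h\eqn{^{-1}}),
#'   `is_exchange` (logical) and `stoich`, a list column of named numeric
#'   vectors (negative coefficient = consumed).
#' @param biomass_reaction_id id of the biomass reaction; must exist in
#'   `reactions`.
#' @param igg_exchange_id optional id of the antibody secretion reaction.
#' @param id model identifier.
#' @return an object of class `chemoflux_network`.
#' @seealso [read_bigg_json()], [augment_with_igg()], [validate_network()]
#' @export
metabolic_network <- function(metabolites, reactions, biomass_reaction_id,
                              igg_exchange_id = NULL, id = "network") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  req_m <- c("id", "name", "compartment")
  req_r <- c("id", "name", "lower_bound", "upper_bound", "is_exchange",
             "stoich")
  if (!all(req_m %in% names(metabolites))) {
    stop("metabolites must have columns: ", paste(req_m, collapse = ", "),
         call. = FALSE)
  }
  if (!all(req_r %in% names(reactions))) {
    stop("reactions must have columns: ", paste(req_r, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(metabolites$id))) stop("empty metabolite id", call. = FALSE)
  refs <- unique(unlist(lapply(reactions$stoich, names)))
  dangling <- setdiff(refs, metabolites$id)
  if (length(dangling) > 0) {
    stop("integrity error: reactions reference unknown metabolites: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (!biomass_reaction_id %in% reactions$id) {
    stop("biomass reaction '", biomass_reaction_id, "' not in model",
         call. = FALSE)
  }
  if (!is.null(igg_exchange_id) && !igg_exchange_id %in% reactions$id) {
    stop("igg exchange reaction '", igg_exchange_id, "' not in model",
         call. = FALSE)
  }
  structure(
    list(metabolites = metabolites, reactions = reactions,
         biomass_reaction_id = biomass_reaction_id,
         igg_exchange_id = igg_exchange_id, id = id),
    class = "chemoflux_network"
  )
}

#' @export
print.chemoflux_network <- function(x, ...) {
  cat("<chemoflux_network> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$is_exchange), " exchange)\n", sep = "")
  cat("  biomass:     ", x$biomass_reaction_id, "\n", sep = "")
  if (!is.null(x$igg_exchange_id)) {
    cat("  IgG secretion: ", x$igg_exchange_id, "\n", sep = "")
  }
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' One row per metabolite, one column per reaction; entry is the signed
#' stoichiometric coefficient.
#'
#' @param net a [metabolic_network()].
#' @return a dense numeric matrix with dimnames (metabolite ids, reaction
#'   ids).
#' @export
stoich_matrix <- function(net) {
  stopifnot(inherits(net, "chemoflux_network"))
  S <- matrix(0, nrow(net$metabolites), nrow(net$reactions),
              dimnames = list(net$metabolites$id, net$reactions$id))
  for (j in seq_len(nrow(net$reactions))) {
    st <- net$reactions$stoich[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Structural integrity report for a network
#'
#' Checks a network for dangling metabolite references, reversed flux bounds
#' (`lower_bound > upper_bound`), duplicate metabolite/reaction ids, empty
#' stoichiometries and exchange reactions touching more than one metabolite.
#' Findings are returned as data, not raised as errors, so degenerate models
#' can be inspected.
#'
#' @param net a network-shaped object (list with `metabolites`, `reactions`).
#' @return a tibble with columns `finding`, `id`, `message`; zero rows for a
#'   structurally valid network.
#' @export
validate_network <- function(net) {
  find <- list()
  add <- function(finding, id, message) {
    find[[length(find) + 1]] <<- tibble::tibble(
      finding = finding, id = id, message = message)
  }
  mets <- net$metabolites
  rxns <- net$reactions
  for (d in unique(mets$id[duplicated(mets$id)])) {
    add("duplicate_metabolite", d, "metabolite id occurs more than once")
  }
  for (d in unique(rxns$id[duplicated(rxns$id)])) {
    add("duplicate_reaction", d, "reaction id occurs more than once")
  }
  refs <- unique(unlist(lapply(rxns$stoich, names)))
  for (d in setdiff(refs, mets$id)) {
    add("dangling_metabolite", d, "referenced by a reaction but not defined")
  }
  for (j in seq_len(nrow(rxns))) {
    if (rxns$lower_bound[j] > rxns$upper_bound[j]) {
      add("bound_violation", rxns$id[j],
          sprintf("lower bound %g exceeds upper bound %g",
                  rxns$lower_bound[j], rxns$upper_bound[j]))
    }
    if (length(rxns$stoich[[j]]) == 0) {
      add("empty_stoichiometry", rxns$id[j], "reaction has no metabolites")
    }
    if (isTRUE(rxns$is_exchange[j]) && length(rxns$stoich[[j]]) != 1) {
      add("exchange_arity", rxns$id[j],
          sprintf("exchange reaction touches %d metabolites",
                  length(rxns$stoich[[j]])))
    }
  }
  if (!is.null(net$biomass_reaction_id) &&
      !net$biomass_reaction_id %in% rxns$id) {
    add("missing_biomass", net$biomass_reaction_id,
        "biomass reaction id does not resolve")
  }
  if (length(find) == 0) {
    return(tibble::tibble(finding = character(), id = character(),
                          message = character()))
  }
  dplyr::bind_rows(find)
}

# Resolve a nutrient id (metabolite id or exchange reaction id) to the id of
# its exchange reaction. Used by the chemostat coupling and the analyses.
resolve_exchange <- function(net, id) {
  rxns <- net$reactions
  if (id %in% rxns$id && rxns$is_exchange[match(id, rxns$id)]) return(id)
  ex <- rxns[rxns$is_exchange, ]
  hit <- vapply(ex$stoich, function(st) {
    length(st) == 1 && names(st) == id
  }, logical(1))
  if (sum(hit) == 1) return(ex$id[hit])
  if (sum(hit) > 1) {
    stop("nutrient '", id, "' has multiple exchange reactions: ",
         paste(ex$id[hit], collapse = ", "), call. = FALSE)
  }
  cand <- paste0("EX_", id)
  if (cand %in% rxns$id) return(cand)
  stop("mapping error: no exchange reaction found for nutrient '", id, "'",
       call. = FALSE)
}
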