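#' Load a constraint-based model from file
#'
#' Reads a genome-scale metabolic model in BiGG-dialect JSON (the format
#' served by the BiGG Models database, e.g. iCHOv1) or SBML Level 3 with the
#' `fbc` flux-bounds package.
#'
#' Exchange reactions are flagged by either convention: the BiGG id prefix
#' `EX_` or being a single-metabolite boundary reaction.
#'
#' @param path path to the model file.
#' @param dialect `"bigg-json"` or `"sbml"`.
#' @param biomass_reaction id of the biomass reaction. If `NULL`, the first
#'   reaction whose id contains "biomass" (case-insensitive), or the reaction
#'   with a non-zero objective coefficient, is used.
#' @param igg_exchange id of the IgG secretion reaction, for models whose
#'   antibody pathway is already present. If `NULL`, a reaction id matching
#'   `EX_igg` (optionally with an SBML `R_` prefix) is detected
#'   automatically.
#' @return a [metabolic_network()].
#' @export
load_model <- function(path, dialect = c("bigg-json", "sbml"),
                       biomass_reaction = NULL, igg_exchange = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(dialect,
    "bigg-json" = read_bigg_json(path, biomass_reaction, igg_exchange),
    "sbml" = read_sbml(path, biomass_reaction, igg_exchange)
  )
}

#' @rdname load_model
#' @export
read_bigg_json <- function(path, biomass_reaction = NULL,
                           igg_exchange = NULL) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("format error: cannot parse BiGG JSON '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("format error: '", path,
         "' lacks a metabolites or reactions section", call. = FALSE)
  }
  mets <- purrr::map_dfr(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("format error: metabolite without id",
                            call. = FALSE)
    tibble::tibble(
      id = m$id,
      name = m$name %||% m$id,
      compartment = m$compartment %||% guess_compartment(m$id)
    )
  })
  rxns <- purrr::map_dfr(doc$reactions, function(r) {
    if (is.null(r$id)) stop("format error: reaction without id",
                            call. = FALSE)
    st <- unlist(r$metabolites)
    if (is.null(st) || length(st) == 0) {
      stop("format error: reaction '", r$id, "' has empty stoichiometry",
           call. = FALSE)
    }
    tibble::tibble(
      id = r$id,
      name = r$name %||% r$id,
      lower_bound = as.numeric(r$lower_bound %||% -1000),
      upper_bound = as.numeric(r$upper_bound %||% 1000),
      objective_coefficient = as.numeric(r$objective_coefficient %||% 0),
      stoich = list(st)
    )
  })
  rxns$is_exchange <- startsWith(rxns$id, "EX_") |
    vapply(rxns$stoich, length, integer(1)) == 1
  finalize_loaded(mets, rxns, biomass_reaction, igg_exchange,
                  id = doc$id %||% basename(path))
}

#' @rdname load_model
#' @export
read_sbml <- function(path, biomass_reaction = NULL, igg_exchange = NULL) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("format error: cannot parse SBML '", path, "': ",
         conditionMessage(e), call. = FALSE)
  })
  ns <- xml2::xml_ns(doc)
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing")) {
    stop("format error: no <model> element in '", path, "'", call. = FALSE)
  }
  # flux-bound parameters (SBML L3 FBC): id -> value
  pars <- xml2::xml_find_all(model, ".//*[local-name()='parameter']")
  parval <- stats::setNames(
    as.numeric(xml2::xml_attr(pars, "value")),
    xml2::xml_attr(pars, "id"))
  sp <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  mets <- tibble::tibble(
    id = xml2::xml_attr(sp, "id"),
    name = dplyr::coalesce(xml2::xml_attr(sp, "name"),
                           xml2::xml_attr(sp, "id")),
    compartment = xml2::xml_attr(sp, "compartment"),
    boundary = xml2::xml_attr(sp, "boundaryCondition") %in% "true"
  )
  rx <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- purrr::map_dfr(rx, function(r) {
    rid <- xml2::xml_attr(r, "id")
    if (is.na(rid)) stop("format error: reaction without id", call. = FALSE)
    refs <- function(tag, sign) {
      sr <- xml2::xml_find_all(
        r, sprintf(".//*[local-name()='%s']/*[local-name()='speciesReference']",
                   tag))
      if (length(sr) == 0) return(numeric(0))
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, xml2::xml_attr(sr, "species"))
    }
    st <- c(refs("listOfReactants", -1), refs("listOfProducts", 1))
    if (length(st) == 0) {
      stop("format error: reaction '", rid, "' has empty stoichiometry",
           call. = FALSE)
    }
    atts <- xml2::xml_attrs(r)
    pick_attr <- function(what) {
      hit <- grep(paste0("(^|:)", what, "$"), names(atts))
      if (length(hit) > 0) atts[[hit[1]]] else NA_character_
    }
    lb_ref <- pick_attr("lowerFluxBound")
    ub_ref <- pick_attr("upperFluxBound")
    rev <- xml2::xml_attr(r, "reversible") %in% "true"
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(parval)) {
      parval[[lb_ref]]
    } else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(parval)) {
      parval[[ub_ref]]
    } else 1000
    tibble::tibble(id = rid,
                   name = xml2::xml_attr(r, "name") %||% rid,
                   lower_bound = lb, upper_bound = ub,
                   objective_coefficient = 0, stoich = list(st))
  })
  # drop boundary species from stoichiometries (their pool is unbalanced)
  bnd <- mets$id[mets$boundary]
  if (length(bnd) > 0) {
    rxns$stoich <- lapply(rxns$stoich, function(st) st[!names(st) %in% bnd])
    keep <- vapply(rxns$stoich, length, integer(1)) > 0
    rxns <- rxns[keep, ]
    mets <- mets[!mets$boundary, ]
  }
  mets$boundary <- NULL
  rxns$is_exchange <- startsWith(rxns$id, "EX_") |
    startsWith(rxns$id, "R_EX_") |
    vapply(rxns$stoich, length, integer(1)) == 1
  finalize_loaded(mets, rxns, biomass_reaction, igg_exchange,
                  id = xml2::xml_attr(model, "id") %||% basename(path))
}

finalize_loaded <- function(mets, rxns, biomass_reaction, igg_exchange,
                            id) {
  if (is.null(igg_exchange)) {
    hit <- grep("^(R_)?EX_igg", rxns$id, value = TRUE)
    if (length(hit) > 0) igg_exchange <- hit[1]
  } else if (!igg_exchange %in% rxns$id) {
    stop("igg exchange reaction '", igg_exchange, "' not in model",
         call. = FALSE)
  }
  if (is.null(biomass_reaction)) {
    hit <- grepl("biomass", rxns$id, ignore.case = TRUE)
    if (!any(hit) && "objective_coefficient" %in% names(rxns)) {
      hit <- rxns$objective_coefficient != 0
    }
    if (!any(hit)) {
      stop("cannot identify the biomass reaction; pass `biomass_reaction`",
           call. = FALSE)
    }
    biomass_reaction <- rxns$id[which(hit)[1]]
  }
  rxns$objective_coefficient <- NULL
  metabolic_network(mets, rxns, biomass_reaction,
                    igg_exchange_id = igg_exchange, id = id)
}

guess_compartment <- function(id) {
  m <- regmatches(id, regexpr("_[a-z][a-z0-9]?$", id))
  if (length(m) == 1 && nzchar(m)) sub("^_", "", m) else "c"
}

#' Write a network as BiGG-dialect JSON
#'
#' Inverse of [read_bigg_json()]: the written file round-trips metabolite and
#' reaction ids, stoichiometries and bounds exactly.
#'
#' @param net a [metabolic_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bigg_json <- function(net, path) {
  stopifnot(inherits(net, "chemoflux_network"))
  mets <- purrr::pmap(net$metabolites, function(id, name, compartment, ...) {
    list(id = id, name = name, compartment = compartment)
  })
  rxns <- purrr::pmap(
    net$reactions,
    function(id, name, lower_bound, upper_bound, is_exchange, stoich, ...) {
      list(id = id, name = name,
           metabolites = as.list(stoich),
           lower_bound = lower_bound, upper_bound = upper_bound,
           objective_coefficient =
             if (id == net$biomass_reaction_id) 1 else 0)
    })
  doc <- list(id = net$id, metabolites = mets, reactions = rxns,
              genes = list(), version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
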