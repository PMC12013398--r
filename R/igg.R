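#' IgG subunit stoichiometry
#'
#' The antibody pathway added to a host model consists of three reactions:
#' subunit synthesis from amino acids with GTP-driven polymerization
#' (`R1`), assembly of `subunits_per_igg` identical half-antibody subunits
#' into one IgG (`R2`), and secretion of the assembled IgG (`R3`). An
#' `igg_stoichiometry` object holds the molar coefficients of `R1` and the
#' assembly ratio of `R2`.
#'
#' The packaged default table (`igg_stoichiometry_synthetic.csv`) carries the
#' published coefficients for Ala (39), Arg (14), GTP (1324), H2O (1326) and
#' H (1326); the remaining amino-acid coefficients are synthetic,
#' IgG-like residue counts constructed to be internally consistent
#' (total residues = GTP/2, H2O = GTP + 2).
#'
#' @param amino_acid_coeffs named numeric, moles of each amino acid per IgG
#'   subunit; all positive.
#' @param gtp_coeff,h2o_coeff moles of GTP and water consumed per subunit.
#' @param byproduct_coeffs named numeric, moles of each byproduct (H, GDP,
#'   Pi, ...) released per subunit.
#' @param subunits_per_igg subunits assembled per IgG molecule (default 2).
#' @return an object of class `igg_stoichiometry`.
#' @export
igg_stoichiometry <- function(amino_acid_coeffs, gtp_coeff, h2o_coeff,
                              byproduct_coeffs = c(H = 1),
                              subunits_per_igg = 2) {
  stopifnot(length(amino_acid_coeffs) > 0,
            !is.null(names(amino_acid_coeffs)))
  coeffs <- c(amino_acid_coeffs, gtp = gtp_coeff, h2o = h2o_coeff,
              byproduct_coeffs, subunits = subunits_per_igg)
  if (any(coeffs <= 0)) {
    stop("all IgG stoichiometric coefficients must be positive",
         call. = FALSE)
  }
  structure(
    list(amino_acid_coeffs = amino_acid_coeffs,
         gtp_coeff = gtp_coeff, h2o_coeff = h2o_coeff,
         byproduct_coeffs = byproduct_coeffs,
         subunits_per_igg = subunits_per_igg),
    class = "igg_stoichiometry"
  )
}

#' @export
print.igg_stoichiometry <- function(x, ...) {
  cat("<igg_stoichiometry>\n")
  cat("  amino acids: ", length(x$amino_acid_coeffs), " (",
      sum(x$amino_acid_coeffs), " residues per subunit)\n", sep = "")
  cat("  GTP: ", x$gtp_coeff, ", H2O: ", x$h2o_coeff, "\n", sep = "")
  cat("  subunits per IgG: ", x$subunits_per_igg, "\n", sep = "")
  invisible(x)
}

#' Read an IgG stoichiometry table
#'
#' Expects a delimited file with columns `species`, `role`
#' (`amino_acid`, `gtp`, `h2o` or `byproduct`) and `coefficient`.
#'
#' @param path path to the CSV file; defaults to the packaged synthetic
#'   full-length IgG table.
#' @param subunits_per_igg see [igg_stoichiometry()].
#' @return an [igg_stoichiometry()] object.
#' @export
read_igg_stoichiometry <- function(path = NULL, subunits_per_igg = 2) {
  if (is.null(path)) {
    path <- system.file("extdata", "igg_stoichiometry_synthetic.csv",
                        package = "chemoflux", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("species", "role", "coefficient")
  if (!all(req %in% names(tab))) {
    stop("stoichiometry file must have columns: ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  pick <- function(role) {
    sub <- tab[tab$role == role, ]
    stats::setNames(sub$coefficient, sub$species)
  }
  aa <- pick("amino_acid")
  gtp <- unname(pick("gtp"))
  h2o <- unname(pick("h2o"))
  if (length(gtp) != 1 || length(h2o) != 1) {
    stop("stoichiometry file must define exactly one gtp and one h2o row",
         call. = FALSE)
  }
  igg_stoichiometry(aa, gtp, h2o, pick("byproduct"), subunits_per_igg)
}

#' Read a species-to-metabolite id mapping
#'
#' Maps the species names used in an IgG stoichiometry table (`Ala`, `Arg`,
#' `GTP`, ...) to model metabolite ids (`ala__L_c`, ...). A mapping for the
#' BiGG cytosolic ids used by iCHOv1 is packaged as `aa_bigg_mapping.csv`.
#'
#' @param path CSV with columns `species`, `metabolite_id`; defaults to the
#'   packaged BiGG mapping.
#' @return named character vector (species -> metabolite id).
#' @export
read_id_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aa_bigg_mapping.csv",
                        package = "chemoflux", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("species", "metabolite_id") %in% names(tab))) {
    stop("mapping file must have columns species, metabolite_id",
         call. = FALSE)
  }
  stats::setNames(tab$metabolite_id, tab$species)
}

# Reaction/metabolite ids introduced by augmentation.
IGG_IDS <- list(subunit = "igg_subunit_c", igg = "igg_c",
                r1 = "IGG_SYNTH", r2 = "IGG_ASSEMBLY", r3 = "EX_igg")

#' Add the IgG synthesis pathway to a network
#'
#' Appends two metabolites (IgG subunit and assembled IgG) and three
#' reactions: `IGG_SYNTH` (R1, subunit synthesis from amino acids, GTP and
#' water, releasing protons and the GTP hydrolysis products), `IGG_ASSEMBLY`
#' (R2, `subunits_per_igg` subunits -> 1 IgG) and `EX_igg` (R3, secretion;
#' lower bound 0, IgG is only produced). Pre-existing reactions and their
#' stoichiometries are untouched, and `igg_exchange_id` is set to `EX_igg`.
#'
#' @param net a [metabolic_network()].
#' @param stoich an [igg_stoichiometry()]; default is the packaged table.
#' @param id_map named character vector mapping stoichiometry species names
#'   to metabolite ids in `net` (see [read_id_mapping()]).
#' @return the augmented network.
#' @export
augment_with_igg <- function(net, stoich = read_igg_stoichiometry(),
                             id_map = read_id_mapping()) {
  stopifnot(inherits(net, "chemoflux_network"),
            inherits(stoich, "igg_stoichiometry"))
  if (any(unlist(IGG_IDS[c("r1", "r2", "r3")]) %in% net$reactions$id)) {
    stop("idempotency error: network already contains the IgG pathway",
         call. = FALSE)
  }
  species <- c(names(stoich$amino_acid_coeffs), "GTP", "H2O",
               names(stoich$byproduct_coeffs))
  missing_map <- setdiff(species, names(id_map))
  if (length(missing_map) > 0) {
    stop("mapping error: no metabolite mapping for: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  target <- id_map[species]
  absent <- setdiff(unique(target), net$metabolites$id)
  if (length(absent) > 0) {
    stop("mapping error: mapped metabolites absent from the network: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  r1 <- c(-stoich$amino_acid_coeffs, -stoich$gtp_coeff, -stoich$h2o_coeff,
          stoich$byproduct_coeffs)
  names(r1) <- unname(id_map[c(names(stoich$amino_acid_coeffs), "GTP", "H2O",
                               names(stoich$byproduct_coeffs))])
  # collapse duplicates (distinct species may map to one metabolite)
  r1 <- tapply(r1, names(r1), sum)
  r1 <- stats::setNames(as.numeric(r1), names(r1))
  r1[IGG_IDS$subunit] <- 1

  mets <- dplyr::bind_rows(
    net$metabolites,
    tibble::tibble(id = c(IGG_IDS$subunit, IGG_IDS$igg),
                   name = c("IgG subunit", "IgG"),
                   compartment = c("c", "c")))
  new_rxns <- tibble::tibble(
    id = c(IGG_IDS$r1, IGG_IDS$r2, IGG_IDS$r3),
    name = c("IgG subunit synthesis", "IgG assembly", "IgG secretion"),
    lower_bound = c(0, 0, 0),
    upper_bound = c(1000, 1000, 1000),
    is_exchange = c(FALSE, FALSE, TRUE),
    stoich = list(
      r1,
      stats::setNames(c(-stoich$subunits_per_igg, 1),
                      c(IGG_IDS$subunit, IGG_IDS$igg)),
      stats::setNames(-1, IGG_IDS$igg))
  )
  metabolic_network(mets, dplyr::bind_rows(net$reactions, new_rxns),
                    net$biomass_reaction_id,
                    igg_exchange_id = IGG_IDS$r3, id = net$id)
}
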