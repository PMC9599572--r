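#' Create a metabolite
#'
#' A metabolite lives in one of two compartments: the cytosol (`"c"`) or the
#' extracellular space (`"e"`). Carbon atom counts are optional and only used
#' for carbon-balance bookkeeping at FBA optima.
#'
#' @param id Unique metabolite identifier within a model (e.g. `"glc_e"`).
#' @param name Human-readable name; defaults to `id`.
#' @param compartment `"cytosol"` or `"extracellular"`.
#' @param carbon_atoms Optional nonnegative integer count of carbon atoms.
#' @return An object of class `cn_metabolite`.
#' @export
metabolite <- function(id, name = id,
                       compartment = c("cytosol", "extracellular"),
                       carbon_atoms = NA_integer_) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.na(carbon_atoms)) {
    stopifnot(carbon_atoms >= 0, carbon_atoms == round(carbon_atoms))
  }
  structure(
    list(id = id, name = name, compartment = compartment,
         carbon_atoms = as.integer(carbon_atoms)),
    class = "cn_metabolite"
  )
}

#' Create a reaction
#'
#' Stoichiometry maps metabolite ids to signed coefficients (negative =
#' consumed). Bounds are fluxes in mmol/gDW/h. Exchange reactions must touch
#' exactly one (extracellular) metabolite; the convention is COBRA-style:
#' `met -> (nothing)` with coefficient -1, so uptake is a negative flux.
#'
#' @param id Reaction identifier.
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound Flux bounds; `lower_bound <= upper_bound`.
#' @param genes Character vector of associated gene ids (may be empty).
#' @param kind One of `"internal"`, `"transport"`, `"exchange"`, `"biomass"`.
#' @return An object of class `cn_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0, upper_bound = 1000,
                     genes = character(),
                     kind = c("internal", "transport", "exchange", "biomass")) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.numeric(stoichiometry), length(stoichiometry) >= 1L,
            !is.null(names(stoichiometry)), all(nzchar(names(stoichiometry))))
  if (anyDuplicated(names(stoichiometry))) {
    stop("duplicate metabolite in stoichiometry of reaction '", id, "'")
  }
  if (lower_bound > upper_bound) {
    stop("reaction '", id, "': lower_bound > upper_bound")
  }
  if (kind == "exchange" && length(stoichiometry) != 1L) {
    stop("exchange reaction '", id, "' must touch exactly one metabolite")
  }
  structure(
    list(id = id, stoichiometry = stoichiometry,
         lower_bound = as.numeric(lower_bound),
         upper_bound = as.numeric(upper_bound),
         genes = as.character(genes), kind = kind),
    class = "cn_reaction"
  )
}

#' Assemble a stoichiometric model
#'
#' @param species_id Species identifier the model belongs to.
#' @param metabolites List of [metabolite()] objects.
#' @param reactions List of [reaction()] objects.
#' @param biomass_id Id(s) of the biomass reaction(s). Single-species models
#'   have exactly one; community models built by [merge_mixed_bag()] retain
#'   one biomass reaction per member.
#' @param community Logical; `TRUE` for merged community models, which are
#'   allowed multiple biomass reactions.
#' @return A validated object of class `cn_model`.
#' @export
stoich_model <- function(species_id, metabolites, reactions, biomass_id,
                         community = FALSE) {
  m <- structure(
    list(species_id = species_id,
         metabolites = metabolites,
         reactions = reactions,
         biomass_id = as.character(biomass_id),
         community = isTRUE(community)),
    class = "cn_model"
  )
  validate_model(m)
  m
}

#' Validate a stoichiometric model
#'
#' Checks id uniqueness, referential integrity of stoichiometries, exchange
#' topology (single extracellular metabolite), and biomass reaction
#' resolution.
#'
#' @param model A `cn_model`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "cn_model"))
  met_ids <- vapply(model$metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "))
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "))
  }
  comp <- stats::setNames(
    vapply(model$metabolites, `[[`, character(1), "compartment"), met_ids)
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(missing, collapse = ", "))
    }
    if (r$kind == "exchange" &&
        comp[[names(r$stoichiometry)]] != "extracellular") {
      stop("exchange reaction '", r$id,
           "' must touch an extracellular metabolite")
    }
  }
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  biomass_rxns <- rxn_ids[kinds == "biomass"]
  if (!model$community && length(biomass_rxns) != 1L) {
    stop("model '", model$species_id, "' must have exactly one biomass ",
         "reaction, found ", length(biomass_rxns))
  }
  if (!all(model$biomass_id %in% biomass_rxns)) {
    stop("biomass_id does not resolve to a biomass-kind reaction")
  }
  if (!setequal(model$biomass_id, biomass_rxns)) {
    stop("biomass reactions not listed in biomass_id: ",
         paste(setdiff(biomass_rxns, model$biomass_id), collapse = ", "))
  }
  invisible(model)
}

#' @export
print.cn_model <- function(x, ...) {
  cat(sprintf("<cn_model> %s%s: %d metabolites, %d reactions, biomass: %s\n",
              x$species_id, if (x$community) " (community)" else "",
              length(x$metabolites), length(x$reactions),
              paste(x$biomass_id, collapse = ", ")))
  invisible(x)
}

#' Define a growth medium
#'
#' A minimal-medium specification: carbon-free base nutrients (ammonium,
#' phosphate, sulfate, water, trace elements), given as maximum uptake rates
#' per exchange reaction, plus a single focal carbon source with its own
#' uptake ceiling. Mirrors M9-style cultivation where each substrate is
#' supplied as the sole carbon source with ammonium as the nitrogen source.
#'
#' @param carbon_source Metabolite id of the focal carbon source
#'   (extracellular).
#' @param carbon_uptake_max Maximum uptake flux for the carbon source,
#'   mmol/gDW/h; default 10, applied uniformly across substrates.
#' @param base_nutrients Named numeric vector, exchange reaction id -> max
#'   uptake. Must not contain carbon-bearing compounds.
#' @param name Carbon source name used in niche reports; defaults to the
#'   metabolite id with a trailing `_e` compartment suffix stripped.
#' @return An object of class `cn_medium`.
#' @export
medium_spec <- function(carbon_source, carbon_uptake_max = 10,
                        base_nutrients = default_base_nutrients(),
                        name = NULL) {
  stopifnot(is.character(carbon_source), length(carbon_source) == 1L)
  if (!(carbon_uptake_max > 0)) stop("carbon_uptake_max must be > 0")
  if (length(base_nutrients)) {
    stopifnot(is.numeric(base_nutrients), !is.null(names(base_nutrients)))
  }
  if (is.null(name)) name <- sub("_e$", "", carbon_source)
  structure(
    list(base_nutrients = base_nutrients,
         carbon_source = carbon_source,
         carbon_uptake_max = as.numeric(carbon_uptake_max),
         name = name),
    class = "cn_medium"
  )
}

#' Default carbon-free base nutrients
#'
#' Exchange uptake ceilings for the M9-like mineral base: ammonium (18 mM in
#' the emulated cultivation, here an unrestrictive uptake ceiling), phosphate,
#' sulfate and water. None carries carbon.
#'
#' @return Named numeric vector of exchange reaction id -> max uptake.
#' @export
default_base_nutrients <- function() {
  c(EX_nh4_e = 1000, EX_pi_e = 1000, EX_so4_e = 1000, EX_h2o_e = 1000)
}
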