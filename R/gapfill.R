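#' Create a universal reaction set
#'
#' The donor database for gapfilling: a superset of reactions, each with a
#' provenance tag, plus a registry of every metabolite those reactions
#' reference (so that adding a reaction can also add its metabolites).
#' Reaction ids may overlap model ids; an overlap is only legal when the
#' stoichiometries are identical.
#'
#' @param reactions List of [reaction()] objects.
#' @param metabolites List of [metabolite()] objects covering every
#'   metabolite referenced by `reactions`.
#' @param provenance Character vector of provenance tags, one per reaction.
#' @return An object of class `cn_universal`.
#' @export
universal_reaction_set <- function(reactions, metabolites,
                                   provenance = rep("unspecified",
                                                    length(reactions))) {
  stopifnot(length(provenance) == length(reactions))
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(rxn_ids)) stop("duplicate reaction ids in universal set")
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  referenced <- unique(unlist(lapply(reactions,
                                     function(r) names(r$stoichiometry))))
  missing <- setdiff(referenced, met_ids)
  if (length(missing)) {
    stop("universal set missing metabolite definitions: ",
         paste(missing, collapse = ", "))
  }
  structure(list(reactions = stats::setNames(reactions, rxn_ids),
                 metabolites = stats::setNames(metabolites, met_ids),
                 provenance = stats::setNames(provenance, rxn_ids)),
            class = "cn_universal")
}

#' Create a growth phenotype matrix
#'
#' @param entries Data frame with columns `species_id`, `carbon_source`,
#'   `phenotype` (one of `"growth"`, `"no_growth"`, `"untested"`); at most
#'   one row per (species, carbon source) pair.
#' @return The validated data frame with class `cn_phenotypes`.
#' @export
phenotype_matrix <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("species_id", "carbon_source", "phenotype") %in%
                  names(entries)))
  if (!all(entries$phenotype %in% c("growth", "no_growth", "untested"))) {
    stop("phenotype must be growth/no_growth/untested")
  }
  key <- paste(entries$species_id, entries$carbon_source)
  if (anyDuplicated(key)) stop("duplicate (species, carbon source) entries")
  class(entries) <- c("cn_phenotypes", "data.frame")
  entries
}

same_stoichiometry <- function(a, b, tol = 1e-9) {
  setequal(names(a), names(b)) && all(abs(a[names(a)] - b[names(a)]) <= tol)
}

# Add universal reactions (and any metabolites they need) to a model.
add_reactions <- function(model, rxn_ids, universal) {
  met_ids <- vapply(model$metabolites, `[[`, character(1), "id")
  have <- vapply(model$reactions, `[[`, character(1), "id")
  for (rid in rxn_ids) {
    r <- universal$reactions[[rid]]
    if (is.null(r)) stop("reaction '", rid, "' not in universal set")
    if (rid %in% have) next
    for (mid in names(r$stoichiometry)) {
      if (!(mid %in% met_ids)) {
        model$metabolites <- c(model$metabolites,
                               list(universal$metabolites[[mid]]))
        met_ids <- c(met_ids, mid)
      }
    }
    model$reactions <- c(model$reactions, list(r))
    have <- c(have, rid)
  }
  validate_model(model)
  model
}

# Candidate reactions from the universal set absent from the model. A
# universal reaction whose id is present in the model with identical
# stoichiometry is skipped; a conflicting overlap is an error.
gapfill_candidates <- function(model, universal) {
  have <- stats::setNames(model$reactions,
                          vapply(model$reactions, `[[`, character(1), "id"))
  keep <- character()
  for (rid in sort(names(universal$reactions))) {
    r <- universal$reactions[[rid]]
    if (rid %in% names(have)) {
      if (!same_stoichiometry(r$stoichiometry, have[[rid]]$stoichiometry)) {
        stop("universal reaction '", rid,
             "' conflicts with the model's stoichiometry for that id")
      }
      next
    }
    keep <- c(keep, rid)
  }
  keep
}

# Exact minimal-cardinality search: try subsets of candidates in increasing
# size; within a size, subsets are visited in lexicographic order of the
# (sorted) candidate ids so the result is deterministic. Falls back to a
# greedy best-improvement pass when the subset count explodes.
min_additions_for_growth <- function(model, medium, candidates, universal,
                                     threshold = 1e-6, max_additions = 3,
                                     subset_cap = 20000) {
  if (predicts_growth(model, medium, threshold)) {
    return(list(added = character(), status = "already_growing"))
  }
  n <- length(candidates)
  if (n == 0L) return(list(added = NULL, status = "unresolvable"))
  for (k in seq_len(min(max_additions, n))) {
    if (choose(n, k) <= subset_cap) {
      sets <- utils::combn(candidates, k, simplify = FALSE)
      for (s in sets) {
        m2 <- add_reactions(model, s, universal)
        if (predicts_growth(m2, medium, threshold)) {
          return(list(added = s, status = "resolved"))
        }
      }
    } else {
      g <- greedy_additions(model, medium, candidates, universal,
                            threshold, max_additions)
      return(g)
    }
  }
  list(added = NULL, status = "unresolvable")
}

greedy_additions <- function(model, medium, candidates, universal,
                             threshold, max_additions) {
  added <- character()
  current <- model
  for (i in seq_len(max_additions)) {
    best <- NULL
    best_obj <- -Inf
    for (rid in setdiff(candidates, added)) {
      m2 <- add_reactions(current, rid, universal)
      obj <- run_fba(m2, medium)$objective
      if (obj > best_obj + 1e-12) {
        best_obj <- obj
        best <- rid
      }
    }
    if (is.null(best)) break
    added <- c(added, best)
    current <- add_reactions(current, best, universal)
    if (best_obj > threshold) {
      return(list(added = added, status = "resolved"))
    }
  }
  list(added = NULL, status = "unresolvable")
}

#' Phenotype-guided gapfilling of a draft model
#'
#' Iterates over media in ascending carbon-source order; for every medium
#' where the species' recorded phenotype is `"growth"` but the draft does
#' not grow, adds a minimal-cardinality set of universal reactions restoring
#' growth (exact subset search in increasing size; deterministic tie-break
#' by reaction id). Additions accumulate across media. Gapfilling only ever
#' adds reactions: `"no_growth"` phenotypes are never enforced, and any
#' residual false growth on negative media is recorded in the report.
#'
#' @param draft A `cn_model` draft.
#' @param universal A [universal_reaction_set()].
#' @param phenotypes A [phenotype_matrix()] covering this species.
#' @param media List of [medium_spec()] objects covering every positive
#'   phenotype carbon source.
#' @param threshold Growth threshold passed to [predicts_growth()].
#' @param max_additions Largest addition set searched per medium.
#' @return List with `model` (the gapfilled model) and `report`
#'   (class `cn_gapfill_report`): `species_id`, ordered
#'   `added_reaction_ids`, a per-carbon-source `resolution` data frame, and
#'   `false_growth_pre`/`false_growth_post` (negative-phenotype sources
#'   predicted to grow before/after gapfilling).
#' @export
gapfill_model <- function(draft, universal, phenotypes, media,
                          threshold = 1e-6, max_additions = 3) {
  validate_model(draft)
  sources <- vapply(media, `[[`, character(1), "name")
  media <- media[order(sources)]
  sources <- sort(sources)
  ph <- phenotypes[phenotypes$species_id == draft$species_id, , drop = FALSE]
  pos <- ph$carbon_source[ph$phenotype == "growth"]
  neg <- ph$carbon_source[ph$phenotype == "no_growth"]
  if (!all(pos %in% sources)) {
    stop("media do not cover positive phenotype source(s): ",
         paste(setdiff(pos, sources), collapse = ", "))
  }
  false_pre <- character()
  for (src in neg) {
    i <- match(src, sources)
    if (!is.na(i) && predicts_growth(draft, media[[i]], threshold)) {
      false_pre <- c(false_pre, src)
    }
  }
  model <- draft
  added_all <- character()
  status <- character(length(sources))
  names(status) <- sources
  for (i in seq_along(sources)) {
    src <- sources[i]
    if (!(src %in% pos)) {
      status[i] <- "not_requested"
      next
    }
    cand <- gapfill_candidates(model, universal)
    fit <- min_additions_for_growth(model, media[[i]], cand, universal,
                                    threshold, max_additions)
    status[i] <- fit$status
    if (fit$status == "resolved") {
      model <- add_reactions(model, fit$added, universal)
      added_all <- c(added_all, fit$added)
    }
  }
  false_post <- character()
  for (src in neg) {
    i <- match(src, sources)
    if (!is.na(i) && predicts_growth(model, media[[i]], threshold)) {
      false_post <- c(false_post, src)
    }
  }
  report <- structure(
    list(species_id = draft$species_id,
         added_reaction_ids = added_all,
         resolution = data.frame(carbon_source = sources,
                                 status = unname(status),
                                 stringsAsFactors = FALSE),
         false_growth_pre = false_pre,
         false_growth_post = false_post),
    class = "cn_gapfill_report")
  list(model = model, report = report)
}

#' Fraction of growth phenotypes correctly predicted
#'
#' Compares [predicts_growth()] calls against recorded growth/no-growth
#' observations over every non-untested (species, carbon source) entry.
#'
#' @param models List of `cn_model`, one per species (matched by
#'   `species_id`).
#' @param phenotypes A [phenotype_matrix()].
#' @param media List of [medium_spec()] covering every phenotyped carbon
#'   source.
#' @param threshold Growth threshold.
#' @return Fraction in \[0, 1\]; errors when no non-untested entries exist.
#' @export
phenotype_concordance <- function(models, phenotypes, media,
                                  threshold = 1e-6) {
  by_species <- stats::setNames(
    models, vapply(models, `[[`, character(1), "species_id"))
  by_source <- stats::setNames(
    media, vapply(media, `[[`, character(1), "name"))
  tested <- phenotypes[phenotypes$phenotype != "untested", , drop = FALSE]
  if (nrow(tested) == 0L) stop("no non-untested phenotype entries")
  ok <- logical(nrow(tested))
  for (i in seq_len(nrow(tested))) {
    sp <- tested$species_id[i]
    src <- tested$carbon_source[i]
    if (is.null(by_species[[sp]])) stop("no model for species '", sp, "'")
    if (is.null(by_source[[src]])) stop("no medium for source '", src, "'")
    pred <- predicts_growth(by_species[[sp]], by_source[[src]], threshold)
    ok[i] <- pred == (tested$phenotype[i] == "growth")
  }
  mean(ok)
}

#' Merge models into a mixed-bag community model
#'
#' Pools all member reactions and metabolites in a single shared compartment
#' pair without species boundaries. Duplicate reaction ids with identical
#' stoichiometry collapse to one reaction with the widest bounds and the
#' union of gene associations; conflicting stoichiometry under one id is a
#' hard error. All member biomass reactions are retained, and FBA on the
#' merged model maximizes their sum.
#'
#' @param models Nonempty list of `cn_model`.
#' @param community_id Species id given to the merged model.
#' @return A `cn_model` with `community = TRUE` (a single input model is
#'   returned unchanged).
#' @export
merge_mixed_bag <- function(models, community_id = "community") {
  stopifnot(is.list(models), length(models) >= 1L)
  if (length(models) == 1L) return(models[[1L]])
  mets <- list()
  rxns <- list()
  for (m in models) {
    validate_model(m)
    for (met in m$metabolites) {
      old <- mets[[met$id]]
      if (is.null(old)) {
        mets[[met$id]] <- met
      } else {
        if (!identical(old$compartment, met$compartment)) {
          stop("metabolite '", met$id, "' has conflicting compartments")
        }
        if (is.na(old$carbon_atoms) && !is.na(met$carbon_atoms)) {
          mets[[met$id]]$carbon_atoms <- met$carbon_atoms
        }
      }
    }
    for (r in m$reactions) {
      old <- rxns[[r$id]]
      if (is.null(old)) {
        rxns[[r$id]] <- r
      } else {
        if (!same_stoichiometry(old$stoichiometry, r$stoichiometry)) {
          stop("reaction id collision with conflicting stoichiometry: '",
               r$id, "'")
        }
        rxns[[r$id]]$lower_bound <- min(old$lower_bound, r$lower_bound)
        rxns[[r$id]]$upper_bound <- max(old$upper_bound, r$upper_bound)
        rxns[[r$id]]$genes <- union(old$genes, r$genes)
      }
    }
  }
  biomass_ids <- names(rxns)[vapply(rxns, `[[`, character(1), "kind") ==
                               "biomass"]
  stoich_model(species_id = community_id,
               metabolites = unname(mets),
               reactions = unname(rxns),
               biomass_id = biomass_ids,
               community = TRUE)
}
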