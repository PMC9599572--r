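#' Write a stoichiometric model to JSON
#'
#' One document per species: metabolites with compartments and carbon
#' counts, reactions with stoichiometry maps, bounds, gene associations and
#' kinds. [read_model_json()] is its exact inverse.
#'
#' @param model A `cn_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_model(model)
  doc <- list(
    species_id = model$species_id,
    community = model$community,
    biomass_id = as.list(model$biomass_id),
    metabolites = lapply(model$metabolites, function(m) {
      list(id = m$id, name = m$name, compartment = m$compartment,
           carbon_atoms = if (is.na(m$carbon_atoms)) NULL else m$carbon_atoms)
    }),
    reactions = lapply(model$reactions, function(r) {
      list(id = r$id, stoichiometry = as.list(r$stoichiometry),
           lower_bound = r$lower_bound, upper_bound = r$upper_bound,
           genes = as.list(r$genes), kind = r$kind)
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a stoichiometric model from JSON
#'
#' @param path Path to a model JSON written by [write_model_json()] (or
#'   conforming to the same schema).
#' @return A validated `cn_model`.
#' @export
read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) {
                    stop("cannot parse model JSON '", path, "': ",
                         conditionMessage(e))
                  })
  need <- c("species_id", "metabolites", "reactions", "biomass_id")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    stop("model JSON '", path, "' missing element(s): ",
         paste(missing, collapse = ", "))
  }
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(m$id, name = m$name %||% m$id, compartment = m$compartment,
               carbon_atoms = m$carbon_atoms %||% NA_integer_)
  })
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    reaction(r$id, st, lower_bound = r$lower_bound,
             upper_bound = r$upper_bound,
             genes = unlist(r$genes) %||% character(), kind = r$kind)
  })
  stoich_model(doc$species_id, mets, rxns,
               biomass_id = unlist(doc$biomass_id),
               community = isTRUE(doc$community))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a medium specification as TSV
#'
#' Columns: `id` (exchange reaction id for base nutrients, metabolite id
#' for the carbon source), `max_uptake`, `role` (`base` or `carbon`).
#'
#' @param medium A [medium_spec()].
#' @param path TSV path.
#' @return `path` invisibly / a `cn_medium`.
#' @export
write_medium_tsv <- function(medium, path) {
  df <- rbind(
    data.frame(id = names(medium$base_nutrients),
               max_uptake = unname(medium$base_nutrients), role = "base",
               stringsAsFactors = FALSE),
    data.frame(id = medium$carbon_source,
               max_uptake = medium$carbon_uptake_max, role = "carbon",
               stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_medium_tsv
#' @export
read_medium_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "max_uptake", "role")
  if (!all(need %in% names(df))) {
    stop("medium TSV '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  carbon <- df[df$role == "carbon", , drop = FALSE]
  if (nrow(carbon) != 1L) {
    stop("medium TSV '", path, "' must have exactly one carbon row")
  }
  base <- df[df$role == "base", , drop = FALSE]
  medium_spec(carbon$id, carbon_uptake_max = carbon$max_uptake,
              base_nutrients = stats::setNames(base$max_uptake, base$id))
}

#' Write / read a growth phenotype matrix as TSV
#'
#' @param phenotypes A [phenotype_matrix()].
#' @param path TSV path with columns `species_id`, `carbon_source`,
#'   `phenotype`.
#' @return `path` invisibly / a `cn_phenotypes`.
#' @export
write_phenotypes_tsv <- function(phenotypes, path) {
  utils::write.table(as.data.frame(phenotypes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  phenotype_matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE))
}

# --- SBML subset reader -----------------------------------------------------

sbml_reject <- function(path, what) {
  stop("unsupported SBML construct in '", path, "': ", what,
       " (this reader supports a flat species/reactions/fbc-bounds subset)")
}

#' Read a flat SBML subset into a stoichiometric model
#'
#' Supports a minimal constraint-based subset: up to two compartments
#' (mapped to cytosol/extracellular), species, reactions with
#' reactant/product stoichiometries, and flux bounds either as fbc
#' attributes resolving to listOfParameters or as the `reversible` flag
#' defaults. Any construct outside that subset (kinetic laws, rules,
#' events, boundary-condition species, more than two compartments) is
#' rejected loudly rather than silently dropped.
#'
#' @param path Path to an SBML XML file.
#' @param biomass_id Reaction id to treat as the biomass objective; by
#'   default the unique reaction whose id contains "biomass"
#'   (case-insensitive).
#' @return A validated `cn_model`.
#' @export
read_model_sbml <- function(path, biomass_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) {
                    stop("cannot parse SBML '", path, "': ",
                         conditionMessage(e))
                  })
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) {
    stop("no <model> element in '", path, "'")
  }
  for (bad in c("listOfRules", "listOfEvents", "listOfConstraints",
                "listOfInitialAssignments", "listOfFunctionDefinitions")) {
    if (length(xml2::xml_find_all(doc, paste0(".//", bad)))) {
      sbml_reject(path, bad)
    }
  }
  if (length(xml2::xml_find_all(doc, ".//kineticLaw"))) {
    sbml_reject(path, "kineticLaw")
  }
  comps <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  comp_ids <- xml2::xml_attr(comps, "id")
  if (length(comp_ids) > 2L) {
    sbml_reject(path, paste0(length(comp_ids), " compartments"))
  }
  comp_map <- vapply(comp_ids, function(id) {
    if (grepl("^(c|cytosol|cytoplasm)$", id)) "cytosol"
    else if (grepl("^(e|extracellular|external)$", id)) "extracellular"
    else sbml_reject(path, paste0("compartment id '", id, "'"))
  }, character(1))
  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  attr_or <- function(node, attr, default) {
    v <- xml2::xml_attr(node, attr)
    if (is.na(v)) default else v
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- lapply(sp_nodes, function(s) {
    if (identical(xml2::xml_attr(s, "boundaryCondition"), "true")) {
      sbml_reject(path, "boundaryCondition species")
    }
    sid <- xml2::xml_attr(s, "id")
    metabolite(sid, name = attr_or(s, "name", sid),
               compartment = comp_map[[xml2::xml_attr(s, "compartment")]])
  })
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    st <- numeric()
    for (ref in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      co <- as.numeric(attr_or(ref, "stoichiometry", "1"))
      st[xml2::xml_attr(ref, "species")] <- -co
    }
    for (ref in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      sp_id <- xml2::xml_attr(ref, "species")
      co <- as.numeric(attr_or(ref, "stoichiometry", "1"))
      prev <- if (sp_id %in% names(st)) st[[sp_id]] else 0
      st[sp_id] <- prev + co
    }
    if (!length(st)) sbml_reject(path, paste0("empty reaction '", rid, "'"))
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lb <- if (!is.na(lb_ref)) pvals[[lb_ref]] else if (rev) -1000 else 0
    ub <- if (!is.na(ub_ref)) pvals[[ub_ref]] else 1000
    kind <- if (grepl("biomass", rid, ignore.case = TRUE)) "biomass"
            else if (length(st) == 1L) "exchange"
            else "internal"
    reaction(rid, st, lower_bound = lb, upper_bound = ub, kind = kind)
  })
  rxn_ids <- vapply(rxns, `[[`, character(1), "id")
  if (is.null(biomass_id)) {
    biomass_id <- rxn_ids[vapply(rxns, `[[`, character(1), "kind") ==
                            "biomass"]
  }
  model_id <- attr_or(model_node, "id", "sbml_model")
  stoich_model(model_id, mets, rxns, biomass_id = biomass_id)
}

# --- fixture + pipeline -----------------------------------------------------

#' Write a complete synthetic fixture directory
#'
#' Materializes a ground-truth-known benchmark: model JSONs under
#' `models/`, the media panel under `media/`, `phenotypes.tsv`,
#' `counts.tsv` (+ sample metadata and gene map), `metabolites.tsv`,
#' `truth.json`, and a `manifest.json` recording the seed and parameters.
#' Identical seeds produce byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param seed Master seed; the count and metabolite streams derive from it.
#' @param design A [consortium_design()]; default [default_consortium_design()].
#' @param deletions_per_model,n_decoys Passed to [gen_draft_and_universal()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dir, seed = 42L,
                          design = default_consortium_design(seed),
                          deletions_per_model = 1:3, n_decoys = 15) {
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "media"), showWarnings = FALSE)
  cons <- gen_consortium(design)
  for (sp in names(cons$models)) {
    write_model_json(cons$models[[sp]],
                     file.path(dir, "models", paste0(sp, ".json")))
  }
  for (src in names(cons$media)) {
    write_medium_tsv(cons$media[[src]],
                     file.path(dir, "media", paste0(src, ".tsv")))
  }
  ph <- gen_phenotypes(design, noise = 0, seed = seed)
  write_phenotypes_tsv(ph, file.path(dir, "phenotypes.tsv"))
  cnt <- gen_counts(seed = seed, species = design$species,
                    abundances = design$abundances)
  utils::write.table(cnt$em$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(cnt$em$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = names(cnt$em$gene_map),
               species_id = unname(cnt$em$gene_map)),
    file.path(dir, "gene_map.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  met <- gen_metabolites(seed = seed)
  utils::write.table(met$abund, file.path(dir, "metabolites.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  truth <- list(fundamental = cons$truth$fundamental,
                realized = cons$truth$realized,
                abundances = as.list(cons$truth$abundances),
                planted_degs = cnt$truth$planted,
                planted_metabolites = met$truth$planted)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(seed = seed,
                   package_version = as.character(
                     utils::packageVersion("commniche")),
                   n_species = length(design$species),
                   carbon_panel = design$carbon_panel,
                   deletions_per_model = deletions_per_model,
                   n_decoys = n_decoys)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Pipeline order mirrors the modeled study: isolate models -> gapfilling
#' against phenotypes -> mixed-bag merge -> fundamental/realized niches,
#' then transcriptome and metabolite summaries. All stages are
#' deterministic given the config seed; outputs are TSV/JSON under
#' `config$out_dir` plus a run manifest recording seeds and thresholds.
#'
#' @param config List with `seed`, `out_dir`, and optionally
#'   `growth_threshold` (default 1e-6), `alpha` (0.05), `min_fold` (2),
#'   `design` (a [consortium_design()]), `gapfill` (logical, default TRUE),
#'   `deletions_per_model`, `n_decoys`.
#' @return List of result objects (`niche`, `gapfill_reports`,
#'   `concordance`, `degs`, `abundance`, `metabolites`, `coverage`),
#'   invisibly; side effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  seed <- as.integer(config$seed %||% 42L)
  thr <- config$growth_threshold %||% 1e-6
  alpha <- config$alpha %||% 0.05
  min_fold <- config$min_fold %||% 2
  design <- config$design %||% default_consortium_design(seed)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  cons <- gen_consortium(design)
  ph <- gen_phenotypes(design, noise = 0, seed = seed)
  reports <- list()
  models <- cons$models
  if (isTRUE(config$gapfill %||% TRUE)) {
    bench <- gen_draft_and_universal(
      models, design,
      deletions_per_model = config$deletions_per_model %||% 1:3,
      n_decoys = config$n_decoys %||% 15, seed = seed)
    models <- bench$drafts
    for (sp in names(models)) {
      gf <- gapfill_model(models[[sp]], bench$universal, ph,
                          unname(cons$media), threshold = thr)
      models[[sp]] <- gf$model
      reports[[sp]] <- gf$report
    }
  }
  conc <- phenotype_concordance(unname(models), ph, unname(cons$media), thr)
  community <- merge_mixed_bag(unname(models))
  profile <- niche_table(unname(models), community, unname(cons$media), thr)
  utils::write.table(profile$table, file.path(out, "niche_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(reports, function(r) {
      list(species_id = r$species_id,
           added_reaction_ids = as.list(r$added_reaction_ids),
           false_growth_pre = as.list(r$false_growth_pre),
           false_growth_post = as.list(r$false_growth_post))
    }),
    file.path(out, "gapfill_reports.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  cnt <- gen_counts(seed = seed, species = design$species,
                    abundances = design$abundances)
  degs <- call_degs(cnt$em, alpha = alpha, min_fold = min_fold)
  utils::write.table(degs, file.path(out, "degs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  deg_summary <- do.call(rbind, lapply(split(degs, degs$species_id),
    function(d) {
      data.frame(species_id = d$species_id[1],
                 n_degs = sum(d$is_deg, na.rm = TRUE),
                 n_genes = nrow(d),
                 pct_degs = deg_percentage(sum(d$is_deg, na.rm = TRUE),
                                           nrow(d)),
                 stringsAsFactors = FALSE)
    }))
  utils::write.table(deg_summary, file.path(out, "deg_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- abundance_profile(cnt$em)
  utils::write.table(ab$summary, file.path(out, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  met <- gen_metabolites(seed = seed)
  md <- metabolite_diff(met$abund, met$groups, alpha = alpha)
  utils::write.table(md, file.path(out, "metabolites.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(seed = seed, growth_threshold = thr, alpha = alpha,
                   min_fold = min_fold, concordance = conc,
                   package_version = as.character(
                     utils::packageVersion("commniche")),
                   outputs = c("niche_table.tsv", "gapfill_reports.json",
                               "degs.tsv", "deg_summary.tsv",
                               "abundance.tsv", "metabolites.tsv"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(niche = profile, gapfill_reports = reports,
                 concordance = conc, degs = degs, deg_summary = deg_summary,
                 abundance = ab, metabolites = md))
}
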