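#' Carbon substrate registry for synthetic consortia
#'
#' Twelve-substrate panel mirroring a chitin-degradation growth screen:
#' the chitin polymer, its monomer NAG, sugars, and amino acids, with carbon
#' atom counts and substrate classes. Chitin is modeled per tetrameric unit
#' (hydrolyzed to two chitobiose, each to two NAG).
#'
#' @return Data frame with columns `id`, `carbon_atoms`, `class`.
#' @export
substrate_registry <- function() {
  data.frame(
    id = c("chitin", "glucose", "nag", "fructose", "sucrose", "maltose",
           "xylose", "arabinose", "serine", "glycine", "alanine",
           "glutamate"),
    carbon_atoms = c(32L, 6L, 8L, 6L, 12L, 12L, 5L, 5L, 3L, 2L, 3L, 5L),
    class = c("polymer", "monomer", "monomer", "monomer", "disaccharide",
              "disaccharide", "monomer", "monomer", "monomer", "monomer",
              "monomer", "monomer"),
    stringsAsFactors = FALSE)
}

#' Specify a consortium design
#'
#' The ground-truth blueprint a synthetic consortium is generated from:
#' which carbon sources each species is designed to metabolize (its
#' designed fundamental niche), which species carry the extracellular
#' polymer-hydrolysis machinery (degraders), and designed community
#' abundances.
#'
#' Design rules enforced: every niche is a subset of the panel; a panel
#' containing the chitin polymer requires at least one degrader; a species
#' designed to grow on chitin must both degrade it and consume NAG (so
#' `chitin` in a niche implies membership in `degraders` and `nag` in the
#' same niche); conversely a degrader that consumes NAG necessarily grows
#' on chitin, so `nag` in a degrader's niche implies `chitin` there too.
#'
#' @param niches Named list, species id -> character vector of designed
#'   substrates.
#' @param degraders Character vector of species carrying chitinase
#'   machinery.
#' @param abundances Named numeric vector of designed community abundance
#'   fractions (summing to 1).
#' @param carbon_panel Character vector of panel substrates (default: the
#'   full 12-substrate registry).
#' @param seed Integer seed recorded with the design.
#' @return Object of class `cn_design`.
#' @export
consortium_design <- function(niches, degraders = character(),
                              abundances = NULL,
                              carbon_panel = substrate_registry()$id,
                              seed = 42L) {
  species <- names(niches)
  stopifnot(!is.null(species), all(nzchar(species)))
  reg <- substrate_registry()
  unknown <- setdiff(carbon_panel, reg$id)
  if (length(unknown)) {
    stop("unknown panel substrate(s): ", paste(unknown, collapse = ", "))
  }
  for (sp in species) {
    extra <- setdiff(niches[[sp]], carbon_panel)
    if (length(extra)) {
      stop("designed niche of '", sp, "' is not a subset of the panel: ",
           paste(extra, collapse = ", "))
    }
    if ("chitin" %in% niches[[sp]]) {
      if (!(sp %in% degraders)) {
        stop("species '", sp, "' is designed to grow on chitin but is not ",
             "a degrader: no one would cleave the polymer for it")
      }
      if (!("nag" %in% niches[[sp]])) {
        stop("species '", sp, "' is designed to grow on chitin but cannot ",
             "consume NAG, its breakdown product")
      }
    }
    if (sp %in% degraders && "nag" %in% niches[[sp]] &&
        !("chitin" %in% niches[[sp]])) {
      stop("degrader '", sp, "' consumes NAG, so it would grow on chitin; ",
           "add chitin to its designed niche or drop its degrader role")
    }
  }
  if ("chitin" %in% carbon_panel &&
      any(vapply(niches, function(n) "chitin" %in% n, logical(1))) &&
      length(degraders) == 0L) {
    stop("panel contains a polymer but the design names no degrader")
  }
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(1 / length(species), length(species)),
                                  species)
  }
  stopifnot(setequal(names(abundances), species),
            abs(sum(abundances) - 1) < 1e-9)
  structure(list(species = species, carbon_panel = carbon_panel,
                 niches = niches, degraders = degraders,
                 abundances = abundances[species], seed = as.integer(seed)),
            class = "cn_design")
}

#' The default 8-species, 12-substrate consortium design
#'
#' Designed fundamental niche sizes decrease strictly from the broadest
#' generalist (an Ensifer-like species, 11 substrates) down to specialist
#' chitin degraders (a Dyadobacter-like species, 3 substrates), with
#' designed community abundances decreasing in the same order. Four species
#' carry chitinase machinery.
#'
#' @param seed Seed recorded with the design (default 42).
#' @return A [consortium_design()].
#' @export
default_consortium_design <- function(seed = 42L) {
  niches <- list(
    ensifer_like = c("glucose", "nag", "fructose", "sucrose", "maltose",
                     "xylose", "arabinose", "serine", "glycine", "alanine",
                     "glutamate"),
    streptomyces_like = c("glucose", "nag", "fructose", "sucrose", "maltose",
                          "xylose", "arabinose", "serine", "glycine",
                          "alanine"),
    variovorax_like = c("chitin", "glucose", "nag", "fructose", "sucrose",
                        "maltose", "xylose", "arabinose", "serine"),
    rhodococcus_like = c("chitin", "glucose", "nag", "fructose", "sucrose",
                         "maltose", "xylose", "arabinose"),
    sinorhizobium_like = c("chitin", "glucose", "nag", "fructose", "sucrose",
                           "maltose"),
    sphingopyxis_like = c("glucose", "nag", "fructose", "xylose", "serine"),
    neorhizobium_like = c("glucose", "fructose", "serine", "glycine"),
    dyadobacter_like = c("chitin", "glucose", "nag"))
  abundances <- c(ensifer_like = 0.34, streptomyces_like = 0.22,
                  variovorax_like = 0.15, rhodococcus_like = 0.10,
                  sinorhizobium_like = 0.07, sphingopyxis_like = 0.05,
                  neorhizobium_like = 0.04, dyadobacter_like = 0.03)
  consortium_design(niches,
                    degraders = c("variovorax_like", "rhodococcus_like",
                                  "sinorhizobium_like", "dyadobacter_like"),
                    abundances = abundances, seed = seed)
}

# Shared reaction templates. Reactions keep the same id across species so
# the mixed-bag merge collapses duplicates; gene associations stay
# species-specific and are unioned on merge.
substrate_pathway <- function(src, species_id, reg, degrader) {
  ca <- stats::setNames(reg$carbon_atoms, reg$id)
  cls <- stats::setNames(reg$class, reg$id)
  mets <- list()
  rxns <- list()
  gene <- function(tag) paste0(species_id, "_", tag)
  add_met <- function(id, carbon, comp) {
    mets[[id]] <<- metabolite(id, compartment = comp, carbon_atoms = carbon)
  }
  add_exchange <- function(met_id) {
    rid <- paste0("EX_", met_id)
    rxns[[rid]] <<- reaction(rid, stats::setNames(-1, met_id),
                             lower_bound = -1000, upper_bound = 1000,
                             kind = "exchange")
  }
  add_monomer <- function(m) {
    e <- paste0(m, "_e"); c_ <- paste0(m, "_c")
    add_met(e, ca[[m]], "extracellular")
    add_met(c_, ca[[m]], "cytosol")
    add_exchange(e)
    rxns[[paste0("T_", m)]] <<- reaction(
      paste0("T_", m), stats::setNames(c(-1, 1), c(e, c_)),
      genes = gene(paste0("t_", m)), kind = "transport")
    rxns[[paste0("CAT_", m)]] <<- reaction(
      paste0("CAT_", m),
      stats::setNames(c(-1, ca[[m]] / 6), c(c_, "precursor_c")),
      genes = gene(paste0("cat_", m)), kind = "internal")
  }
  add_catabolism_only <- function(m) {
    c_ <- paste0(m, "_c")
    add_met(c_, ca[[m]], "cytosol")
    rxns[[paste0("CAT_", m)]] <<- reaction(
      paste0("CAT_", m),
      stats::setNames(c(-1, ca[[m]] / 6), c(c_, "precursor_c")),
      genes = gene(paste0("cat_", m)), kind = "internal")
  }
  if (cls[[src]] == "monomer") {
    add_monomer(src)
  } else if (cls[[src]] == "disaccharide") {
    e <- paste0(src, "_e"); c_ <- paste0(src, "_c")
    add_met(e, ca[[src]], "extracellular")
    add_met(c_, ca[[src]], "cytosol")
    add_exchange(e)
    rxns[[paste0("T_", src)]] <- reaction(
      paste0("T_", src), stats::setNames(c(-1, 1), c(e, c_)),
      genes = gene(paste0("t_", src)), kind = "transport")
    products <- if (src == "sucrose") c("glucose", "fructose")
                else c("glucose", "glucose")
    st <- stats::setNames(-1, c_)
    for (p in unique(products)) {
      st[paste0(p, "_c")] <- sum(products == p)
    }
    rxns[[paste0("HYD_", src)]] <- reaction(
      paste0("HYD_", src), st, genes = gene(paste0("hyd_", src)),
      kind = "internal")
    for (p in unique(products)) add_catabolism_only(p)
  } else if (src == "chitin") {
    # extracellular hydrolysis chain: chitin -> 2 chitobiose -> 4 NAG
    add_met("chitin_e", ca[["chitin"]], "extracellular")
    add_met("chitobiose_e", 16L, "extracellular")
    add_exchange("chitin_e")
    add_exchange("chitobiose_e")
    rxns[["CHIT_chitin"]] <- reaction(
      "CHIT_chitin", c(chitin_e = -1, chitobiose_e = 2),
      genes = gene("chiA"), kind = "internal")
    rxns[["CHITOB_chitobiose"]] <- reaction(
      "CHITOB_chitobiose", c(chitobiose_e = -1, nag_e = 2),
      genes = gene("hex20"), kind = "internal")
    add_met("nag_e", 8L, "extracellular")
    add_exchange("nag_e")
  }
  list(metabolites = mets, reactions = rxns)
}

# Assemble one species model that grows exactly on its designed substrates.
build_species_model <- function(species_id, niche, degrader, reg) {
  mets <- list(precursor_c = metabolite("precursor_c", compartment = "cytosol",
                                        carbon_atoms = 6L))
  rxns <- list()
  absorb <- function(part) {
    for (id in names(part$metabolites)) mets[[id]] <<- part$metabolites[[id]]
    for (id in names(part$reactions)) rxns[[id]] <<- part$reactions[[id]]
  }
  for (src in sort(setdiff(niche, "chitin"))) {
    absorb(substrate_pathway(src, species_id, reg, degrader))
  }
  if (degrader) {
    absorb(substrate_pathway("chitin", species_id, reg, degrader))
  }
  bio_id <- paste0("biomass_", species_id)
  rxns[[bio_id]] <- reaction(bio_id, c(precursor_c = -1),
                             kind = "biomass")
  stoich_model(species_id, unname(mets), unname(rxns), bio_id)
}

#' Growth media panel for a set of carbon sources
#'
#' @param sources Character vector of substrate ids (default the full
#'   registry panel).
#' @param carbon_uptake_max Uniform uptake ceiling per substrate
#'   (mmol/gDW/h), default 10 (substrates standardized by molarity).
#' @return Named list of [medium_spec()].
#' @export
panel_media <- function(sources = substrate_registry()$id,
                        carbon_uptake_max = 10) {
  stats::setNames(
    lapply(sources, function(s) {
      medium_spec(paste0(s, "_e"), carbon_uptake_max = carbon_uptake_max)
    }), sources)
}

# carbon source ids in media are metabolite ids (<src>_e); map back
medium_source_name <- function(medium) sub("_e$", "", medium$carbon_source)

#' Generate a ground-truth-known synthetic consortium
#'
#' Builds one stoichiometric model per designed species such that FBA
#' predicts growth exactly on the designed substrate set, and derives the
#' community-level ground truth: the realized niche is the union of the
#' designed niches, plus chitin whenever some member degrades the polymer
#' and some member consumes NAG (cross-feeding).
#'
#' @param design A [consortium_design()].
#' @return List with `models` (named list of `cn_model`), `media` (named
#'   list of [medium_spec()] over the panel), `design`, and `truth` (list
#'   with `fundamental`, `realized`, `abundances`).
#' @export
gen_consortium <- function(design) {
  stopifnot(inherits(design, "cn_design"))
  reg <- substrate_registry()
  models <- stats::setNames(
    lapply(design$species, function(sp) {
      build_species_model(sp, design$niches[[sp]],
                          sp %in% design$degraders, reg)
    }), design$species)
  union_niche <- sort(unique(unlist(design$niches)))
  realized <- union_niche
  consumes_nag <- any(vapply(design$niches, function(n) "nag" %in% n,
                             logical(1)))
  if ("chitin" %in% design$carbon_panel && length(design$degraders) &&
      consumes_nag) {
    realized <- sort(unique(c(realized, "chitin")))
  }
  list(models = models,
       media = panel_media(design$carbon_panel),
       design = design,
       truth = list(fundamental = design$niches,
                    realized = realized,
                    abundances = design$abundances))
}

#' Derive drafts and a universal reaction set from ground-truth models
#'
#' Deletes 1-3 substrate-critical reactions per model (transport steps for
#' monomers and disaccharides, the chitinase step for chitin), each breaking
#' growth on one designed substrate, and assembles the universal donor set
#' as the union of all ground-truth reactions plus mass-balanced decoy
#' reactions on disconnected metabolites.
#'
#' @param models Named list of ground-truth `cn_model`s (from
#'   [gen_consortium()]).
#' @param design The matching [consortium_design()].
#' @param deletions_per_model Integer vector of allowed deletion counts; one
#'   count is sampled per model (default `1:3`).
#' @param n_decoys Number of decoy reactions in the universal set.
#' @param seed Seed for the deletion/decoy stream.
#' @return List with `drafts`, `universal` (a
#'   [universal_reaction_set()]), and `truth` (named list species ->
#'   deleted reaction ids).
#' @export
gen_draft_and_universal <- function(models, design, deletions_per_model = 1:3,
                                    n_decoys = 15, seed = 42L) {
  set.seed(seed)
  stopifnot(all(deletions_per_model >= 0))
  all_rxns <- list()
  all_mets <- list()
  for (m in models) {
    for (met in m$metabolites) all_mets[[met$id]] <- met
    for (r in m$reactions) {
      if (r$kind == "biomass") next  # biomass is never a gapfill donor
      old <- all_rxns[[r$id]]
      if (!is.null(old) &&
          !same_stoichiometry(old$stoichiometry, r$stoichiometry)) {
        stop("conflicting stoichiometry for shared reaction '", r$id, "'")
      }
      if (is.null(old)) {
        all_rxns[[r$id]] <- r
      } else {
        all_rxns[[r$id]]$genes <- union(old$genes, r$genes)
      }
    }
  }
  decoy_rxns <- list()
  decoy_mets <- list()
  for (i in seq_len(n_decoys)) {
    a <- sprintf("decoy%02d_a_c", i)
    b <- sprintf("decoy%02d_b_c", i)
    decoy_mets[[a]] <- metabolite(a, compartment = "cytosol")
    decoy_mets[[b]] <- metabolite(b, compartment = "cytosol")
    rid <- sprintf("DECOY_%02d", i)
    decoy_rxns[[rid]] <- reaction(rid, stats::setNames(c(-1, 1), c(a, b)),
                                  kind = "internal")
  }
  universal <- universal_reaction_set(
    reactions = c(unname(all_rxns), unname(decoy_rxns)),
    metabolites = c(unname(all_mets), unname(decoy_mets)),
    provenance = c(rep("ground_truth", length(all_rxns)),
                   rep("decoy", length(decoy_rxns))))
  keystone <- function(src) {
    if (src == "chitin") "CHIT_chitin" else paste0("T_", src)
  }
  drafts <- models
  truth <- stats::setNames(vector("list", length(models)), names(models))
  for (sp in names(models)) {
    niche <- design$niches[[sp]]
    k <- if (length(deletions_per_model) == 1L) deletions_per_model
         else sample(deletions_per_model, 1L)
    k <- min(k, length(niche))
    if (k > length(niche)) {
      stop("requested deletions exceed removable reactions for '", sp, "'")
    }
    if (k == 0L) {
      truth[[sp]] <- character()
      next
    }
    targets <- vapply(sort(sample(niche, k)), keystone, character(1))
    m <- models[[sp]]
    keep <- vapply(m$reactions, function(r) !(r$id %in% targets), logical(1))
    m$reactions <- m$reactions[keep]
    validate_model(m)
    drafts[[sp]] <- m
    truth[[sp]] <- unname(targets)
  }
  list(drafts = drafts, universal = universal, truth = truth)
}

#' Generate a growth phenotype matrix from a design
#'
#' Ground-truth phenotypes (growth iff the substrate is in the designed
#' niche) with optional symmetric label noise.
#'
#' @param design A [consortium_design()].
#' @param noise Probability of flipping each growth/no-growth label.
#' @param seed Seed for the noise stream.
#' @return A [phenotype_matrix()].
#' @export
gen_phenotypes <- function(design, noise = 0, seed = 42L) {
  set.seed(seed)
  grid <- expand.grid(species_id = design$species,
                      carbon_source = design$carbon_panel,
                      stringsAsFactors = FALSE)
  truth <- mapply(function(sp, src) src %in% design$niches[[sp]],
                  grid$species_id, grid$carbon_source)
  if (noise > 0) {
    flip <- stats::runif(length(truth)) < noise
    truth <- xor(truth, flip)
  }
  grid$phenotype <- ifelse(truth, "growth", "no_growth")
  phenotype_matrix(grid)
}

#' Simulate a two-time-point metatranscriptome count matrix
#'
#' Negative-binomial counts around species-abundance-scaled gene means for
#' two groups (70 h and 118 h) with planted differentially expressed genes
#' at a stated effect size and optional per-species abundance shifts
#' between groups.
#'
#' @param n_genes_per_species Genes simulated per species.
#' @param n_planted_degs Total number of planted DEGs (alternating up/down
#'   by `effect_fold`).
#' @param effect_fold Fold effect (> 1) applied at 118 h to planted genes.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_reps Replicates per time point.
#' @param abundance_shifts Optional named numeric vector of per-species
#'   abundance fold changes applied at 118 h before renormalization.
#' @param seed Seed for the whole draw.
#' @param species Species ids; default the 8-species design.
#' @param abundances Baseline abundance fractions (named, sum 1); default
#'   the design's abundances.
#' @param depth Expected total reads per sample.
#' @return List with `em` (an [expression_matrix()]) and `truth` (planted
#'   gene table and true per-group abundance fractions).
#' @export
gen_counts <- function(n_genes_per_species = 300, n_planted_degs = 30,
                       effect_fold = 4, dispersion = 0.1, n_reps = 3,
                       abundance_shifts = NULL, seed = 1L,
                       species = NULL, abundances = NULL, depth = 3e5) {
  stopifnot(effect_fold > 1, dispersion > 0)
  set.seed(seed)
  if (is.null(species)) {
    d <- default_consortium_design()
    species <- d$species
    abundances <- d$abundances
  }
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(1 / length(species), length(species)),
                                  species)
  }
  shifts <- stats::setNames(rep(1, length(species)), species)
  if (!is.null(abundance_shifts)) {
    shifts[names(abundance_shifts)] <- abundance_shifts
  }
  ab70 <- abundances / sum(abundances)
  ab118 <- abundances * shifts
  ab118 <- ab118 / sum(ab118)
  genes <- as.vector(vapply(species, function(sp) {
    sprintf("%s_g%04d", sp, seq_len(n_genes_per_species))
  }, character(n_genes_per_species)))
  gene_map <- stats::setNames(rep(species, each = n_genes_per_species), genes)
  rel <- stats::rlnorm(length(genes), meanlog = 0, sdlog = 1)
  for (sp in species) {
    idx <- gene_map == sp
    rel[idx] <- rel[idx] / sum(rel[idx])
  }
  planted <- sort(sample(genes, n_planted_degs))
  dir <- rep(c(1, -1), length.out = n_planted_degs)
  fold_vec <- stats::setNames(rep(1, length(genes)), genes)
  fold_vec[planted] <- effect_fold ^ dir
  sample_ids <- c(sprintf("t70_r%d", seq_len(n_reps)),
                  sprintf("t118_r%d", seq_len(n_reps)))
  samples <- data.frame(
    sample_id = sample_ids,
    time_point = rep(c("70h", "118h"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2),
    stringsAsFactors = FALSE)
  mu70 <- depth * ab70[gene_map] * rel
  mu118 <- depth * ab118[gene_map] * rel * fold_vec
  counts <- matrix(0L, nrow = length(genes), ncol = length(sample_ids),
                   dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    mu <- if (samples$time_point[j] == "70h") mu70 else mu118
    counts[, j] <- stats::rnbinom(length(genes), mu = mu,
                                  size = 1 / dispersion)
  }
  em <- expression_matrix(counts, samples, gene_map)
  truth <- list(
    planted = data.frame(gene_id = planted,
                         direction = ifelse(dir > 0, "up", "down"),
                         fold = effect_fold ^ dir,
                         stringsAsFactors = FALSE),
    abundance_70h = ab70, abundance_118h = ab118,
    abundance_fold = ab118 / ab70)
  list(em = em, truth = truth)
}

#' Simulate a two-group metabolite abundance table
#'
#' Log-normal abundances for two groups of replicates (70 h and 118 h) with
#' `n_diff` metabolites shifted by `fold` in the second group.
#'
#' @param n_metabolites Number of metabolites.
#' @param n_diff Number of planted differential metabolites.
#' @param fold Fold shift (> 1) applied in group 2.
#' @param sigma Log-scale noise standard deviation (> 0).
#' @param n_reps Replicates per group.
#' @param seed Seed for the whole draw.
#' @return List with `abund` (metabolite x sample matrix), `groups`
#'   (character vector), and `truth` (planted metabolite ids).
#' @export
gen_metabolites <- function(n_metabolites = 100, n_diff = 5, fold = 6.55,
                            sigma = 0.1, n_reps = 5, seed = 1L) {
  stopifnot(fold > 1, sigma > 0, n_diff <= n_metabolites)
  set.seed(seed)
  mets <- sprintf("met%03d", seq_len(n_metabolites))
  base <- exp(stats::runif(n_metabolites, log(1e3), log(1e5)))
  planted <- sort(sample(mets, n_diff))
  sample_ids <- c(sprintf("t70_r%d", seq_len(n_reps)),
                  sprintf("t118_r%d", seq_len(n_reps)))
  groups <- rep(c("70h", "118h"), each = n_reps)
  abund <- matrix(NA_real_, nrow = n_metabolites, ncol = 2 * n_reps,
                  dimnames = list(mets, sample_ids))
  for (j in seq_len(2 * n_reps)) {
    mu <- base
    if (groups[j] == "118h") {
      mu[mets %in% planted] <- mu[mets %in% planted] * fold
    }
    abund[, j] <- mu * exp(stats::rnorm(n_metabolites, 0, sigma))
  }
  list(abund = abund, groups = groups, truth = list(planted = planted,
                                                    fold = fold))
}
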