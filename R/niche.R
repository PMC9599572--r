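#' Fundamental niche of a species
#'
#' The set of panel carbon sources the species is predicted to metabolize
#' for growth on its own (monoculture FBA).
#'
#' @param model A `cn_model`.
#' @param panel List of [medium_spec()], one per candidate carbon source.
#' @param threshold Growth threshold on biomass flux.
#' @return Character vector of carbon source ids (possibly empty).
#' @export
fundamental_niche <- function(model, panel, threshold = 1e-6) {
  if (length(panel) == 0L) return(character())
  sources <- vapply(panel, `[[`, character(1), "name")
  grows <- vapply(panel, function(med) predicts_growth(model, med, threshold),
                  logical(1))
  sources[grows]
}

#' Realized niche of a community
#'
#' The growth-supporting subset of the panel for the mixed-bag community
#' model; by monotonicity of the LP optimum under reaction addition it is a
#' superset of every member's fundamental niche.
#'
#' @param community A community `cn_model` built by [merge_mixed_bag()].
#' @param panel List of [medium_spec()].
#' @param threshold Growth threshold.
#' @return Character vector of carbon source ids.
#' @export
realized_niche <- function(community, panel, threshold = 1e-6) {
  fundamental_niche(community, panel, threshold)
}

#' Fundamental/realized niche table for a consortium
#'
#' Computes every member's fundamental niche, the community realized niche,
#' niche sizes and realized deltas (how many extra carbon sources the
#' community opens to each member). Species are ordered from largest to
#' smallest fundamental niche, ties broken lexicographically by species id.
#'
#' @param models Nonempty list of member `cn_model`s.
#' @param community Mixed-bag community model of the members.
#' @param panel List of [medium_spec()].
#' @param threshold Growth threshold.
#' @return An object of class `cn_niche_profile`: list with `fundamental`
#'   (named list of source sets), `realized` (character vector), `sizes`,
#'   `realized_delta` (named integer vectors, ordered as above), and `table`
#'   (data frame rendering).
#' @export
niche_table <- function(models, community, panel, threshold = 1e-6) {
  stopifnot(length(models) >= 1L)
  species <- vapply(models, `[[`, character(1), "species_id")
  fund <- stats::setNames(
    lapply(models, fundamental_niche, panel = panel, threshold = threshold),
    species)
  realized <- realized_niche(community, panel, threshold)
  for (sp in species) {
    if (!all(fund[[sp]] %in% realized)) {
      stop("invariant violated: fundamental niche of '", sp,
           "' is not contained in the realized niche")
    }
  }
  sizes <- vapply(fund, length, integer(1))
  ord <- order(-sizes, names(sizes))
  sizes <- sizes[ord]
  fund <- fund[ord]
  delta <- length(realized) - sizes
  tab <- data.frame(
    species_id = names(sizes),
    niche_size = unname(sizes),
    realized_delta = unname(delta),
    sources = vapply(fund, function(s) paste(sort(s), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fundamental = fund, realized = sort(realized),
                 sizes = sizes, realized_delta = delta, table = tab),
            class = "cn_niche_profile")
}

#' @export
print.cn_niche_profile <- function(x, ...) {
  cat(sprintf("<cn_niche_profile> realized niche: %d sources\n",
              length(x$realized)))
  print(x$table, ...)
  invisible(x)
}

#' Rank agreement between niche sizes and abundances
#'
#' Spearman rank correlation (average ranks for ties) between per-species
#' fundamental niche sizes and community abundances, quantifying how well
#' ranking by niche size aligns with ranking by abundance.
#'
#' @param sizes Named numeric/integer vector, species -> niche size.
#' @param abundances Named numeric vector, species -> abundance fraction;
#'   must have the same names as `sizes`.
#' @return Correlation in \[-1, 1\].
#' @export
rank_agreement <- function(sizes, abundances) {
  if (is.null(names(sizes)) || is.null(names(abundances)) ||
      !setequal(names(sizes), names(abundances))) {
    stop("sizes and abundances must be named over the same species")
  }
  if (length(sizes) < 3L) stop("need at least 3 species")
  stats::cor(as.numeric(sizes), as.numeric(abundances[names(sizes)]),
             method = "spearman")
}
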