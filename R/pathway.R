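#' Define an annotation-matching pathway
#'
#' A pathway is an ordered list of steps, each assigned to an early/mid/late
#' stage and carrying a nonempty set of accepted annotation terms (EC, KO,
#' GH or CE identifiers). A species covers a step when any of its annotation
#' terms matches any accepted term.
#'
#' @param steps List of lists with fields `step_id`, `stage` (`"early"`,
#'   `"mid"` or `"late"`), and `terms` (list of `list(type=, term=)`).
#' @param name,version Metadata carried along for reporting.
#' @return An object of class `cn_pathway`.
#' @export
pathway_definition <- function(steps, name = "pathway", version = "1.0") {
  stopifnot(length(steps) >= 1L)
  ids <- vapply(steps, `[[`, character(1), "step_id")
  if (anyDuplicated(ids)) stop("duplicate step ids")
  for (s in steps) {
    if (!(s$stage %in% c("early", "mid", "late"))) {
      stop("step '", s$step_id, "': stage must be early/mid/late")
    }
    if (length(s$terms) == 0L) {
      stop("step '", s$step_id, "' has no accepted terms")
    }
  }
  structure(list(name = name, version = version, steps = steps),
            class = "cn_pathway")
}

#' The shipped 8-step chitin/NAG pathway
#'
#' Loads the versioned pathway configuration distributed with the package:
#' chitin binding, GH18 and GH19 chitinases, CE4 deacetylation (early);
#' GH20/GH3 beta-N-acetylhexosaminidase and the NAG PTS transporter (mid);
#' NAG-6-phosphate deacetylase and glucosamine kinase (late). The config is
#' a plain JSON file and can be edited or replaced via `path`.
#'
#' @param path Path to a pathway JSON config; defaults to the shipped file.
#' @return A `cn_pathway` with exactly 8 steps under the default config.
#' @export
chitin_pathway <- function(path = system.file("extdata", "chitin_pathway.json",
                                              package = "commniche")) {
  cfg <- jsonlite::read_json(path)
  steps <- lapply(cfg$steps, function(s) {
    list(step_id = s$step_id, stage = s$stage,
         terms = lapply(s$terms, function(t) list(type = t$type,
                                                  term = t$term)))
  })
  pathway_definition(steps, name = cfg$name, version = cfg$version)
}

# Term syntax per type; the Unicode minus occasionally found in printed EC
# numbers is normalized to an ASCII dash before validation.
normalize_term <- function(term) gsub("−", "-", trimws(term))

term_is_valid <- function(type, term) {
  term <- normalize_term(term)
  switch(type,
         EC = grepl("^([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$",
                    term),
         KO = grepl("^K[0-9]{5}$", term),
         GH = grepl("^GH[0-9]+$", term),
         CE = grepl("^CE[0-9]+$", term),
         FALSE)
}

# EC matching honors wildcard fields: a '-' in either term's field matches
# any value of the other ("4.2.2.-" matches "4.2.2.17"). Non-EC terms match
# by identity within the same type.
terms_match <- function(type_a, term_a, type_b, term_b) {
  if (type_a != type_b) return(FALSE)
  a <- normalize_term(term_a)
  b <- normalize_term(term_b)
  if (type_a != "EC") return(identical(a, b))
  fa <- strsplit(a, ".", fixed = TRUE)[[1]]
  fb <- strsplit(b, ".", fixed = TRUE)[[1]]
  if (length(fa) != 4L || length(fb) != 4L) return(FALSE)
  all(fa == fb | fa == "-" | fb == "-")
}

#' Build an annotation table
#'
#' @param species_id Species the annotations belong to.
#' @param gene_id,term_type,term Parallel vectors; `term_type` is one of
#'   `"EC"`, `"KO"`, `"GH"`, `"CE"`.
#' @return Data frame with class `cn_annotations`.
#' @export
annotation_table <- function(species_id, gene_id, term_type, term) {
  stopifnot(length(gene_id) == length(term_type),
            length(term_type) == length(term))
  out <- data.frame(species_id = rep_len(species_id, length(gene_id)),
                    gene_id = as.character(gene_id),
                    term_type = as.character(term_type),
                    term = as.character(term),
                    stringsAsFactors = FALSE)
  class(out) <- c("cn_annotations", "data.frame")
  out
}

#' Score a species' annotations against a pathway
#'
#' A step is covered iff any syntactically valid annotation term matches any
#' of the step's accepted terms; the score counts distinct covered steps,
#' not genes. Malformed terms are skipped with a warning, never fatal.
#'
#' @param table Annotation data frame with columns `species_id`, `gene_id`,
#'   `term_type`, `term` (a single species).
#' @param pathway A `cn_pathway`, default the shipped chitin/NAG pathway.
#' @return Object of class `cn_coverage`: `species_id`, `covered` (0 to the
#'   number of steps), `covered_steps` (character), `per_stage` (named
#'   integer vector over early/mid/late).
#' @export
score_coverage <- function(table, pathway = chitin_pathway()) {
  stopifnot(is.data.frame(table),
            all(c("species_id", "gene_id", "term_type", "term") %in%
                  names(table)))
  sp <- unique(table$species_id)
  if (length(sp) > 1L) {
    stop("score_coverage expects a single species; see score_coverage_all()")
  }
  if (length(sp) == 0L) sp <- NA_character_
  valid <- logical(nrow(table))
  for (i in seq_len(nrow(table))) {
    valid[i] <- term_is_valid(table$term_type[i], table$term[i])
  }
  if (any(!valid)) {
    warning(sum(!valid), " malformed annotation term(s) skipped for ",
            "species '", sp, "'")
  }
  ann <- table[valid, , drop = FALSE]
  covered <- character()
  stages <- c(early = 0L, mid = 0L, late = 0L)
  for (s in pathway$steps) {
    hit <- FALSE
    for (acc in s$terms) {
      if (hit) break
      for (i in seq_len(nrow(ann))) {
        if (terms_match(ann$term_type[i], ann$term[i], acc$type, acc$term)) {
          hit <- TRUE
          break
        }
      }
    }
    if (hit) {
      covered <- c(covered, s$step_id)
      stages[s$stage] <- stages[s$stage] + 1L
    }
  }
  structure(list(species_id = sp, covered = length(covered),
                 covered_steps = covered, per_stage = stages,
                 n_steps = length(pathway$steps)),
            class = "cn_coverage")
}

#' Score every species in a multi-species annotation table
#'
#' @param table Annotation data frame covering one or more species.
#' @param pathway A `cn_pathway`.
#' @return Named list of `cn_coverage`, one per species.
#' @export
score_coverage_all <- function(table, pathway = chitin_pathway()) {
  sp <- sort(unique(table$species_id))
  stats::setNames(
    lapply(sp, function(s) {
      score_coverage(table[table$species_id == s, , drop = FALSE], pathway)
    }), sp)
}

#' Early/mid/late stage profile across species
#'
#' Tabulates per-stage covered-step counts per species, the summary used to
#' assign species to early/mid/late roles in a decomposition cascade.
#'
#' @param scores List of `cn_coverage` objects from one pathway definition.
#' @return Data frame with columns `species_id`, `early`, `mid`, `late`,
#'   `covered`.
#' @export
stage_profile <- function(scores) {
  out <- data.frame(
    species_id = vapply(scores, `[[`, character(1), "species_id"),
    early = vapply(scores, function(s) s$per_stage[["early"]], integer(1)),
    mid = vapply(scores, function(s) s$per_stage[["mid"]], integer(1)),
    late = vapply(scores, function(s) s$per_stage[["late"]], integer(1)),
    covered = vapply(scores, `[[`, integer(1), "covered"),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' @export
print.cn_coverage <- function(x, ...) {
  cat(sprintf("<cn_coverage> %s: %d/%d steps (early %d, mid %d, late %d)\n",
              x$species_id, x$covered, x$n_steps,
              x$per_stage[["early"]], x$per_stage[["mid"]],
              x$per_stage[["late"]]))
  invisible(x)
}
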