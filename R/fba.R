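# Internal flux cap standing in for "unbounded" directions; optima at or
# beyond ~a tenth of it are treated as unbounded LPs, not biology.
.FLUX_CAP <- 1e6

#' Build the stoichiometric matrix of a model
#'
#' @param model A `cn_model`.
#' @return Dense numeric matrix, metabolites in rows, reactions in columns.
#' @export
stoich_matrix <- function(model) {
  met_ids <- vapply(model$metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(model$reactions, `[[`, character(1), "id")
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

# Medium application: close every exchange for uptake, then reopen the base
# nutrients and the focal carbon source. Secretion (upper bounds) is left as
# the model defines it. Returns the lb/ub vectors, not a modified model.
medium_bounds <- function(model, medium) {
  rxn_ids <- vapply(model$reactions, `[[`, character(1), "id")
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  names(lb) <- names(ub) <- rxn_ids
  kinds <- vapply(model$reactions, `[[`, character(1), "kind")
  for (j in which(kinds == "exchange")) {
    r <- model$reactions[[j]]
    met <- names(r$stoichiometry)
    lb[j] <- 0
    if (r$id %in% names(medium$base_nutrients)) {
      lb[j] <- -abs(medium$base_nutrients[[r$id]])
    }
    if (identical(met, medium$carbon_source)) {
      lb[j] <- -abs(medium$carbon_uptake_max)
    }
  }
  list(lb = lb, ub = ub)
}

# Exchange reaction id for a given extracellular metabolite, or NA.
exchange_for <- function(model, met_id) {
  for (r in model$reactions) {
    if (r$kind == "exchange" && identical(names(r$stoichiometry), met_id)) {
      return(r$id)
    }
  }
  NA_character_
}

# Solve  max c'v  s.t.  S v = 0, lb <= v <= ub  with the package's
# deterministic two-phase simplex (see lp.R).
solve_fba_lp <- function(S, obj, lb, ub) {
  lb2 <- pmax(lb, -.FLUX_CAP)
  ub2 <- pmin(ub, .FLUX_CAP)
  res <- lp_simplex_bounded(S, obj, lb2, ub2)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, fluxes = NULL))
  }
  status <- if (abs(res$objective) >= 0.1 * .FLUX_CAP) "unbounded"
            else "optimal"
  list(status = status, objective = res$objective, fluxes = res$v)
}

#' Run flux balance analysis
#'
#' Maximizes biomass flux subject to steady state (`S v = 0`) and flux
#' bounds, with the medium controlling exchange uptake: every exchange not
#' named by the medium is closed for uptake (lower bound 0) while secretion
#' stays open. For community models the objective is the sum of all member
#' biomass fluxes.
#'
#' @param model A validated `cn_model`.
#' @param medium A [medium_spec()].
#' @param tol Relative steady-state tolerance checked at the optimum.
#' @return An object of class `cn_fba` with fields `status`
#'   (`"optimal"`/`"infeasible"`/`"unbounded"`), `objective` (biomass flux; 0
#'   by convention when infeasible, flagged via `status`), and `fluxes`
#'   (named vector).
#' @export
run_fba <- function(model, medium, tol = 1e-9) {
  validate_model(model)
  stopifnot(inherits(medium, "cn_medium"))
  S <- stoich_matrix(model)
  bnd <- medium_bounds(model, medium)
  rxn_ids <- colnames(S)
  obj <- as.numeric(rxn_ids %in% model$biomass_id)
  sol <- solve_fba_lp(S, obj, bnd$lb, bnd$ub)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, objective = 0,
                          fluxes = stats::setNames(rep(NA_real_, length(rxn_ids)),
                                                   rxn_ids)),
                     class = "cn_fba"))
  }
  v <- stats::setNames(sol$fluxes, rxn_ids)
  resid <- max(abs(S %*% v))
  scale <- max(1, max(abs(v)))
  if (resid > max(tol * scale, 1e-7)) {
    stop("FBA optimum violates steady state: residual ", format(resid))
  }
  objective <- max(0, sol$objective)
  structure(list(status = "optimal", objective = objective, fluxes = v),
            class = "cn_fba")
}

#' @export
print.cn_fba <- function(x, ...) {
  cat(sprintf("<cn_fba> status=%s objective=%.6g\n", x$status, x$objective))
  invisible(x)
}

#' Biomass yield per mmol of carbon source
#'
#' Yield is the optimal biomass flux divided by the realized uptake flux of
#' the focal carbon source (gDW per mmol substrate in the model's arbitrary
#' biomass units). Zero uptake with zero biomass gives yield 0; positive
#' biomass without carbon uptake is a conservation violation and errors.
#'
#' @inheritParams run_fba
#' @return Single numeric yield.
#' @export
biomass_yield <- function(model, medium) {
  res <- run_fba(model, medium)
  if (res$status != "optimal") return(0)
  ex_id <- exchange_for(model, medium$carbon_source)
  uptake <- if (is.na(ex_id)) 0 else max(0, -res$fluxes[[ex_id]])
  if (uptake <= 1e-9) {
    if (res$objective > 1e-6) {
      stop("positive biomass with zero carbon uptake: carbon from nowhere ",
           "in model '", model$species_id, "' on ", medium$carbon_source)
    }
    return(0)
  }
  res$objective / uptake
}

#' Does the model grow on a medium?
#'
#' Strict threshold on the optimal biomass flux; infeasible LPs count as no
#' growth. The default cutoff 1e-6 separates numerical noise from growth.
#'
#' @inheritParams run_fba
#' @param threshold Positive growth cutoff on biomass flux.
#' @return Logical.
#' @export
predicts_growth <- function(model, medium, threshold = 1e-6) {
  stopifnot(threshold > 0)
  res <- run_fba(model, medium)
  if (res$status != "optimal") return(FALSE)
  res$objective > threshold
}
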