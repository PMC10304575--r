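# Flux balance analysis and flux variability analysis over the package's
# LP contract, plus the dietary perturbation experiment driver.

#' Flux balance analysis
#'
#' Optimizes the model's objective reaction subject to the steady-state
#' constraint S v = 0 and the reaction flux bounds. The direction
#' (maximize/minimize) is taken from the model's objective.
#'
#' @param model A validated `metabolic_model`.
#' @param tol LP tolerance passed to the solver.
#' @return An object of class `flux_solution`: list with `status`
#'   (`"optimal"`, `"infeasible"`, `"unbounded"`), `objective_value`, a named
#'   flux vector `fluxes` (mmol/larva/day; the biomass flux is 1/day), and
#'   `residual`, the steady-state infinity-norm of S v.
#' @export
fba <- function(model, tol = 1e-9) {
  validate_model(model)
  S <- as.matrix(stoichiometric_matrix(model))
  rxns <- model$reactions
  obj <- as.numeric(rxns$id == model$objective$reaction)
  sense <- if (model$objective$direction == "maximize") "max" else "min"
  res <- solve_lp(obj, S, rep(0, nrow(S)), rxns$lower_bound, rxns$upper_bound,
                  sense = sense, tol = tol)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = stats::setNames(rep(NA_real_, nrow(rxns)), rxns$id),
                          residual = NA_real_),
                     class = "flux_solution"))
  }
  v <- stats::setNames(res$x, rxns$id)
  structure(list(status = "optimal",
                 objective_value = res$objective,
                 fluxes = v,
                 residual = max(abs(S %*% res$x))),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s", x$status))
  if (x$status == "optimal") {
    cat(sprintf("   objective: %.6g   ||S v||_inf: %.2e", x$objective_value, x$residual))
  }
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, minimizes and maximizes its flux subject to
#' steady state, the flux bounds, and the requirement that the objective
#' flux stays at or above `fraction` of the FBA optimum (at or below, for a
#' minimization objective). The default fraction of 0.9 asks for the flux
#' range attainable while maintaining 90% of the maximal growth rate.
#'
#' @param model A validated `metabolic_model`.
#' @param fraction Fraction of the optimum to maintain, in (0, 1].
#' @param reactions Character vector of reaction ids; `NULL` = all reactions.
#' @param tol LP tolerance.
#' @return An object of class `fva_result`: data frame `ranges` with columns
#'   `reaction`, `min_flux`, `max_flux`, plus fields `fraction_of_optimum`
#'   and `reference_optimum`.
#' @export
fva <- function(model, fraction = 0.9, reactions = NULL, tol = 1e-9) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  base <- fba(model, tol = tol)
  if (base$status != "optimal") {
    stop(sprintf("FVA base problem is %s", base$status))
  }
  opt <- base$objective_value
  rxns <- model$reactions
  if (is.null(reactions)) reactions <- rxns$id
  rxn_index(model, reactions)

  lb <- rxns$lower_bound
  ub <- rxns$upper_bound
  k_obj <- match(model$objective$reaction, rxns$id)
  if (model$objective$direction == "maximize") {
    lb[k_obj] <- max(lb[k_obj], fraction * opt)
  } else {
    ub[k_obj] <- min(ub[k_obj], fraction * opt)
  }
  # Guard against roundoff making the tightened problem empty.
  if (lb[k_obj] > ub[k_obj]) lb[k_obj] <- ub[k_obj]

  S <- as.matrix(stoichiometric_matrix(model))
  zero <- rep(0, nrow(S))
  mins <- maxs <- numeric(length(reactions))
  for (i in seq_along(reactions)) {
    e <- as.numeric(rxns$id == reactions[i])
    lo <- solve_lp(e, S, zero, lb, ub, sense = "min", tol = tol)
    hi <- solve_lp(e, S, zero, lb, ub, sense = "max", tol = tol)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop(sprintf("FVA subproblem for reaction '%s' is %s",
                   reactions[i],
                   if (lo$status != "optimal") lo$status else hi$status))
    }
    mins[i] <- lo$objective
    maxs[i] <- hi$objective
  }
  # The two LPs are solved independently; snap out harmless roundoff
  # inversions so min_flux <= max_flux always holds.
  swap <- mins > maxs
  if (any(swap)) {
    mid <- (mins[swap] + maxs[swap]) / 2
    mins[swap] <- maxs[swap] <- mid
  }
  structure(list(
    ranges = data.frame(reaction = reactions, min_flux = mins, max_flux = maxs,
                        stringsAsFactors = FALSE),
    fraction_of_optimum = fraction,
    reference_optimum = opt),
    class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat(sprintf("<fva_result> %d reaction(s) at %.0f%% of optimum %.6g\n",
              nrow(x$ranges), 100 * x$fraction_of_optimum, x$reference_optimum))
  print(utils::head(x$ranges, 10))
  if (nrow(x$ranges) > 10) cat(sprintf("  ... %d more\n", nrow(x$ranges) - 10))
  invisible(x)
}

#' Percent change between two objective values
#'
#' `100 * (perturbed - reference) / reference`, the convention used to
#' report growth-rate responses to dietary perturbations.
#'
#' @param reference,perturbed Either optimal `flux_solution` objects or bare
#'   objective values.
#' @return Percent change (not rounded; callers format for display).
#' @examples
#' growth_change_percent(0.029, 0.051) # 75.86%
#' @export
growth_change_percent <- function(reference, perturbed) {
  val <- function(x, what) {
    if (inherits(x, "flux_solution")) {
      if (x$status != "optimal") stop(sprintf("%s solution is %s", what, x$status))
      x$objective_value
    } else as.numeric(x)
  }
  ref <- val(reference, "reference")
  per <- val(perturbed, "perturbed")
  if (ref == 0) stop("reference objective is zero; percent change undefined")
  100 * (per - ref) / ref
}

#' Run a dietary perturbation experiment
#'
#' Applies a diet, runs reference FBA, scales the scenario's uptake bounds
#' by `factor` (doubling, in the standard experiments), reruns FBA, and
#' reports the growth-rate change. When fatty-acid drain reactions are
#' given, FVA at `fva_fraction` of each state's optimum yields the
#' attainable synthesis-rate ranges for both diets.
#'
#' @param model A `metabolic_model` whose exchanges follow the package's
#'   naming (see [exchange_id()]), or any model when `targets` is given.
#' @param base_bounds An [exchange_bounds()] object for the reference diet.
#' @param scenario One of `"doubled_glucose"`, `"doubled_EAA"`,
#'   `"doubled_single_AA"`.
#' @param single_aa Amino-acid name (e.g. `"Valine"`) for
#'   `"doubled_single_AA"`.
#' @param targets Optional explicit character vector of exchange ids to
#'   scale, overriding the scenario's default resolution.
#' @param factor Scale factor applied to the targeted uptake bounds.
#' @param fva_fraction Fraction of optimum maintained during drain FVA.
#' @param fa_drains Character vector of fatty-acid drain reaction ids, or
#'   `NULL` to skip the FVA stage.
#' @param eaa Character vector of essential-amino-acid names used by
#'   `"doubled_EAA"`.
#' @return List with `scenario`, `reference` and `perturbed` flux solutions,
#'   `growth_change_percent`, and (when `fa_drains` given) `fva_reference`
#'   and `fva_perturbed`.
#' @export
run_perturbation_experiment <- function(model, base_bounds, scenario,
                                        single_aa = NULL, targets = NULL,
                                        factor = 2, fva_fraction = 0.9,
                                        fa_drains = NULL,
                                        eaa = essential_amino_acids()) {
  scenario <- match.arg(scenario,
                        c("doubled_glucose", "doubled_EAA", "doubled_single_AA"))
  if (is.null(targets)) {
    targets <- switch(scenario,
      doubled_glucose = exchange_id("Glucose"),
      doubled_EAA = vapply(eaa, exchange_id, character(1)),
      doubled_single_AA = {
        if (is.null(single_aa)) stop("scenario 'doubled_single_AA' needs single_aa")
        exchange_id(single_aa)
      })
  }
  missing <- setdiff(targets, names(base_bounds))
  if (length(missing) > 0) {
    stop(sprintf("scenario targets not present in diet bounds: %s",
                 paste(missing, collapse = ", ")))
  }
  ref_model <- apply_diet(model, base_bounds)
  ref <- fba(ref_model)
  if (ref$status != "optimal") stop("reference diet gives no optimal solution")
  pert_bounds <- scale_uptake(base_bounds, targets, factor)
  pert_model <- apply_diet(model, pert_bounds)
  pert <- fba(pert_model)
  if (pert$status != "optimal") stop("perturbed diet gives no optimal solution")

  out <- list(scenario = scenario,
              targets = targets,
              reference = ref,
              perturbed = pert,
              growth_change_percent = growth_change_percent(ref, pert))
  if (!is.null(fa_drains)) {
    out$fva_reference <- fva(ref_model, fraction = fva_fraction,
                             reactions = fa_drains)
    out$fva_perturbed <- fva(pert_model, fraction = fva_fraction,
                             reactions = fa_drains)
  }
  out
}
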