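# Stoichiometric model container. Plain S3: a list with metabolite and
# reaction tables plus a stoichiometry list, mirroring the COBRA data model
# so that SBML/JSON/tabular files round-trip without loss.

#' Construct a stoichiometric metabolic model
#'
#' The central container of the package. A model holds an ordered metabolite
#' table, an ordered reaction table with flux bounds (mmol/larva/day), a
#' stoichiometry map per reaction (negative coefficients = substrates,
#' positive = products), a single objective reaction with a direction, the
#' declared compartments, and an opaque gene list. Gene-protein-reaction
#' (GPR) strings are stored and round-tripped but never evaluated.
#'
#' @param id Model identifier string.
#' @param metabolites `data.frame` with columns `id`, `name`, `compartment`,
#'   `formula` (Hill notation or `NA`), `charge` (integer or `NA`).
#' @param reactions `data.frame` with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr`, `subsystem`.
#' @param stoichiometry Named list, one entry per reaction id, each a named
#'   numeric vector of metabolite coefficients.
#' @param compartments Named character vector mapping compartment token to a
#'   display name.
#' @param objective List with elements `reaction` (a reaction id) and
#'   `direction` (`"maximize"` or `"minimize"`).
#' @param genes Character vector of gene ids.
#' @return An object of class `metabolic_model`.
#' @seealso [read_model()], [stoichiometric_matrix()], [fba()]
#' @export
metabolic_model <- function(id, metabolites, reactions, stoichiometry,
                            compartments, objective, genes = character()) {
  stoichiometry <- lapply(stoichiometry, function(s) {
    stats::setNames(as.numeric(s), names(s))
  })
  reactions$lower_bound <- as.numeric(reactions$lower_bound)
  reactions$upper_bound <- as.numeric(reactions$upper_bound)
  model <- structure(
    list(
      id = as.character(id),
      metabolites = as.data.frame(metabolites, stringsAsFactors = FALSE),
      reactions = as.data.frame(reactions, stringsAsFactors = FALSE),
      stoichiometry = stoichiometry,
      compartments = compartments,
      objective = objective,
      genes = as.character(genes)
    ),
    class = "metabolic_model"
  )
  validate_model(model)
  model
}

# Column templates used by readers and the synthetic generator.
empty_metabolite_frame <- function() {
  data.frame(id = character(), name = character(), compartment = character(),
             formula = character(), charge = integer(),
             stringsAsFactors = FALSE)
}

empty_reaction_frame <- function() {
  data.frame(id = character(), name = character(),
             lower_bound = numeric(), upper_bound = numeric(),
             gpr = character(), subsystem = character(),
             stringsAsFactors = FALSE)
}

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, compartment declarations, formula syntax, bound
#' ordering, non-empty stoichiometries over known metabolites, and that the
#' objective reaction exists. Called by every constructor, reader and
#' mutator; analysis code can assume a validated model.
#'
#' @param model A `metabolic_model`.
#' @return Invisibly `TRUE`; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop(sprintf("duplicate metabolite id: %s",
                 mets$id[duplicated(mets$id)][1]))
  }
  if (anyDuplicated(rxns$id)) {
    stop(sprintf("duplicate reaction id: %s", rxns$id[duplicated(rxns$id)][1]))
  }
  if (length(model$compartments) == 0 || is.null(names(model$compartments))) {
    stop("model must declare named compartments")
  }
  bad_comp <- setdiff(unique(mets$compartment), names(model$compartments))
  if (length(bad_comp) > 0) {
    stop(sprintf("metabolite compartment(s) not declared in model: %s",
                 paste(bad_comp, collapse = ", ")))
  }
  for (i in seq_len(nrow(mets))) {
    f <- mets$formula[i]
    if (!is.na(f) && nzchar(f)) parse_formula(f) # errors on bad syntax
  }
  if (any(rxns$lower_bound > rxns$upper_bound)) {
    bad <- rxns$id[rxns$lower_bound > rxns$upper_bound][1]
    stop(sprintf("reaction '%s' has lower_bound > upper_bound", bad))
  }
  if (!setequal(names(model$stoichiometry), rxns$id) ||
      length(model$stoichiometry) != nrow(rxns)) {
    stop("stoichiometry list must have exactly one entry per reaction id")
  }
  for (rid in rxns$id) {
    st <- model$stoichiometry[[rid]]
    if (length(st) == 0) stop(sprintf("reaction '%s' has empty stoichiometry", rid))
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown) > 0) {
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   rid, paste(unknown, collapse = ", ")))
    }
  }
  obj <- model$objective
  if (is.null(obj$reaction) || !nzchar(obj$reaction)) {
    stop("model objective is empty")
  }
  if (!obj$reaction %in% rxns$id) {
    stop(sprintf("objective reaction '%s' does not exist", obj$reaction))
  }
  if (!obj$direction %in% c("maximize", "minimize")) {
    stop("objective direction must be 'maximize' or 'minimize'")
  }
  invisible(TRUE)
}

#' Stoichiometric matrix of a model
#'
#' Builds the sparse matrix S (rows = metabolites, columns = reactions, in
#' model order) whose entry (i, j) is the coefficient of metabolite i in
#' reaction j. Steady state in FBA is the constraint S v = 0: every internal
#' metabolite's production balances its consumption.
#'
#' @param model A validated `metabolic_model`.
#' @return A `Matrix::sparseMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  met_index <- stats::setNames(seq_along(met_ids), met_ids)
  for (jj in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[jj]]]
    i <- c(i, met_index[names(st)])
    j <- c(j, rep.int(jj, length(st)))
    x <- c(x, unname(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s\n", x$id))
  cat(sprintf("  metabolites: %d   reactions: %d   genes: %d   compartments: %d\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes),
              length(x$compartments)))
  cat(sprintf("  objective: %s %s\n", x$objective$direction, x$objective$reaction))
  invisible(x)
}

#' Set flux bounds on a reaction
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @param lower,upper New bounds (mmol/larva/day); `NULL` leaves a bound as is.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  k <- match(reaction_id, model$reactions$id)
  if (is.na(k)) stop(sprintf("unknown reaction '%s'", reaction_id))
  if (!is.null(lower)) model$reactions$lower_bound[k] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[k] <- upper
  if (model$reactions$lower_bound[k] > model$reactions$upper_bound[k]) {
    stop(sprintf("reaction '%s' would get lower_bound > upper_bound", reaction_id))
  }
  model
}

# Internal: look up reaction row index, with a clear error.
rxn_index <- function(model, reaction_id) {
  k <- match(reaction_id, model$reactions$id)
  if (anyNA(k)) {
    stop(sprintf("unknown reaction id(s): %s",
                 paste(reaction_id[is.na(k)], collapse = ", ")))
  }
  k
}
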