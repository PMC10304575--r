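# Model quality-control statistics: exchange reactions, dead-end
# metabolites, blocked reactions, elemental balance, and the aggregate
# report used for cross-model comparison tables.

#' Find exchange (boundary) reactions
#'
#' An exchange reaction involves exactly one metabolite: it moves matter
#' across the model boundary (uptake when its flux is negative, secretion
#' when positive). Demand/sink pseudo-reactions match the same pattern and
#' are included.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of reaction ids.
#' @export
find_exchange_reactions <- function(model) {
  n_mets <- vapply(model$stoichiometry, length, integer(1))
  model$reactions$id[n_mets[model$reactions$id] == 1L]
}

#' Detect dead-end metabolites
#'
#' A metabolite is a dead end when, given reaction directionalities (bounds),
#' it can only ever be produced or only ever be consumed: no steady-state
#' flux can pass through it. A reversible reaction both produces and
#' consumes each of its metabolites.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of metabolite ids.
#' @export
detect_dead_ends <- function(model) {
  rxns <- model$reactions
  can_produce <- can_consume <- stats::setNames(
    rep(FALSE, nrow(model$metabolites)), model$metabolites$id)
  for (i in seq_len(nrow(rxns))) {
    st <- model$stoichiometry[[rxns$id[i]]]
    fwd <- rxns$upper_bound[i] > 0   # net forward flux possible
    bwd <- rxns$lower_bound[i] < 0   # net backward flux possible
    prods <- names(st)[st > 0]
    subs <- names(st)[st < 0]
    if (fwd) {
      can_produce[prods] <- TRUE
      can_consume[subs] <- TRUE
    }
    if (bwd) {
      can_produce[subs] <- TRUE
      can_consume[prods] <- TRUE
    }
  }
  names(can_produce)[!(can_produce & can_consume)]
}

#' Find blocked reactions
#'
#' A reaction is blocked when its flux is zero in every feasible
#' steady-state solution. Detected by per-reaction flux minimization and
#' maximization (no objective constraint); by default all exchange bounds
#' are first opened to the +/-1000 default so that blockage reflects
#' network topology rather than the applied diet.
#'
#' @param model A `metabolic_model`.
#' @param tolerance Absolute flux below which a reaction counts as blocked.
#' @param open_exchanges Open all exchange bounds before testing (default
#'   `TRUE`); set `FALSE` to assess blockage under the bounds as given.
#' @return Character vector of reaction ids.
#' @export
find_blocked_reactions <- function(model, tolerance = 1e-6,
                                   open_exchanges = TRUE) {
  if (open_exchanges) {
    for (rid in find_exchange_reactions(model)) {
      model <- set_bounds(model, rid, lower = -DEFAULT_BOUND,
                          upper = DEFAULT_BOUND)
    }
  }
  rxns <- model$reactions
  S <- as.matrix(stoichiometric_matrix(model))
  zero <- rep(0, nrow(S))
  blocked <- character(0)
  for (i in seq_len(nrow(rxns))) {
    e <- as.numeric(seq_len(nrow(rxns)) == i)
    hi <- solve_lp(e, S, zero, rxns$lower_bound, rxns$upper_bound, "max")
    if (hi$status == "optimal" && hi$objective > tolerance) next
    lo <- solve_lp(e, S, zero, rxns$lower_bound, rxns$upper_bound, "min")
    if (lo$status == "optimal" && lo$objective < -tolerance) next
    if (hi$status != "optimal" || lo$status != "optimal") {
      stop(sprintf("flux bounds LP for reaction '%s' is %s", rxns$id[i],
                   if (hi$status != "optimal") hi$status else lo$status))
    }
    blocked <- c(blocked, rxns$id[i])
  }
  blocked
}

#' Check elemental balance of every reaction
#'
#' For each reaction and element e, the imbalance is the coefficient-
#' weighted sum of e's atom counts over the reaction's metabolites; a
#' balanced reaction has all-zero imbalances. Reactions touching a
#' metabolite without a parseable formula (absent, or containing
#' pseudo-elements) are reported as `unparseable` rather than balanced.
#' Exchange reactions are intrinsically unbalanced: they create or destroy
#' their metabolite.
#'
#' @param model A `metabolic_model`.
#' @param tolerance Absolute imbalance treated as zero.
#' @return `data.frame` with `reaction`, `balanced`, `unparseable`,
#'   `imbalance` (a compact element: count string, empty when balanced).
#' @export
check_mass_balance <- function(model, tolerance = 1e-9) {
  mets <- model$metabolites
  formulas <- stats::setNames(mets$formula, mets$id)
  weighable <- stats::setNames(
    vapply(mets$formula, formula_is_weighable, logical(1)), mets$id)
  rows <- lapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    if (!all(weighable[names(st)])) {
      return(data.frame(reaction = rid, balanced = FALSE, unparseable = TRUE,
                        imbalance = NA_character_, stringsAsFactors = FALSE))
    }
    total <- sum_elements(unname(st), formulas[names(st)])
    total <- total[abs(total) > tolerance]
    data.frame(reaction = rid,
               balanced = length(total) == 0,
               unparseable = FALSE,
               imbalance = if (length(total) == 0) "" else
                 paste(sprintf("%s: %g", names(total), total), collapse = ", "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate model quality-control report
#'
#' The four comparison statistics used to characterize a metabolic
#' reconstruction: percent dead-end metabolites (of all metabolites),
#' percent blocked reactions, percent elementally unbalanced reactions
#' (unparseable formulas counted as unbalanced; exchanges are intrinsically
#' unbalanced and included), and percent exchange reactions (of all
#' reactions). Percentages are reported to 2 decimals.
#'
#' @param model A `metabolic_model`.
#' @param blocked_open_exchanges Passed to [find_blocked_reactions()].
#' @return An object of class `qc_report`: the four percentages plus the
#'   supporting id lists and model dimensions.
#' @export
qc_report <- function(model, blocked_open_exchanges = TRUE) {
  n_met <- nrow(model$metabolites)
  n_rxn <- nrow(model$reactions)
  dead <- detect_dead_ends(model)
  blocked <- find_blocked_reactions(model, open_exchanges = blocked_open_exchanges)
  balance <- check_mass_balance(model)
  unbal <- balance$reaction[!balance$balanced]
  exch <- find_exchange_reactions(model)
  pct <- function(k, n) round(100 * k / n, 2)
  structure(list(
    model_id = model$id,
    n_metabolites = n_met,
    n_reactions = n_rxn,
    n_genes = length(model$genes),
    pct_dead_end_metabolites = pct(length(dead), n_met),
    pct_blocked_reactions = pct(length(blocked), n_rxn),
    pct_unbalanced_reactions = pct(length(unbal), n_rxn),
    pct_exchange_reactions = pct(length(exch), n_rxn),
    dead_end_metabolites = dead,
    blocked_reactions = blocked,
    unbalanced_reactions = unbal,
    exchange_reactions = exch),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s (%d metabolites, %d reactions, %d genes)\n",
              x$model_id, x$n_metabolites, x$n_reactions, x$n_genes))
  cat(sprintf("  dead-end metabolites: %.2f%%   blocked: %.2f%%   unbalanced: %.2f%%   exchange: %.2f%%\n",
              x$pct_dead_end_metabolites, x$pct_blocked_reactions,
              x$pct_unbalanced_reactions, x$pct_exchange_reactions))
  invisible(x)
}

#' One-row comparison-table form of a QC report
#'
#' @param x A `qc_report`.
#' @return One-row `data.frame` matching the cross-model comparison layout.
#' @export
qc_report_row <- function(x) {
  data.frame(model_id = x$model_id,
             metabolites = x$n_metabolites,
             reactions = x$n_reactions,
             genes = x$n_genes,
             pct_dead_end_metabolites = x$pct_dead_end_metabolites,
             pct_blocked_reactions = x$pct_blocked_reactions,
             pct_unbalanced_reactions = x$pct_unbalanced_reactions,
             pct_exchange_reactions = x$pct_exchange_reactions,
             stringsAsFactors = FALSE)
}
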