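# Independent oracles. These deliberately avoid the package's simplex:
# the LP oracle enumerates candidate vertices of {S v = rhs, lb <= v <= ub}
# by fixing n - rank(S) coordinates at bounds and solving the rest, which
# is exact for the small networks it is used on.

oracle_lp <- function(obj, S, lb, ub, rhs = rep(0, nrow(S)), tol = 1e-7) {
  S <- as.matrix(S)
  n <- ncol(S)
  r <- qr(S)$rank
  k <- n - r
  best <- -Inf
  feasible <- FALSE
  fix_sets <- if (k == 0) list(integer(0)) else utils::combn(n, k, simplify = FALSE)
  for (fs in fix_sets) {
    choices <- if (length(fs) == 0) list(numeric(0)) else {
      grid <- expand.grid(rep(list(1:2), length(fs)))
      lapply(seq_len(nrow(grid)), function(i) {
        ifelse(unlist(grid[i, ]) == 1, lb[fs], ub[fs])
      })
    }
    freev <- setdiff(seq_len(n), fs)
    Sf <- S[, freev, drop = FALSE]
    if (length(freev) > 0 && qr(Sf)$rank < length(freev)) next
    for (vals in choices) {
      b2 <- rhs - (if (length(fs)) as.vector(S[, fs, drop = FALSE] %*% vals) else 0)
      vf <- if (length(freev)) {
        tryCatch(qr.solve(Sf, b2), error = function(e) NULL)
      } else numeric(0)
      if (is.null(vf)) next
      v <- numeric(n)
      v[fs] <- vals
      v[freev] <- vf
      if (max(abs(S %*% v - rhs)) > tol) next
      if (any(v < lb - tol) || any(v > ub + tol)) next
      feasible <- TRUE
      best <- max(best, sum(obj * v))
    }
  }
  if (!feasible) list(status = "infeasible", objective = NA_real_)
  else list(status = "optimal", objective = best)
}

# Oracle FBA on a metabolic_model.
oracle_fba <- function(model) {
  S <- as.matrix(larvaflux::stoichiometric_matrix(model))
  obj <- as.numeric(model$reactions$id == model$objective$reaction)
  if (model$objective$direction == "minimize") obj <- -obj
  res <- oracle_lp(obj, S, model$reactions$lower_bound, model$reactions$upper_bound)
  if (res$status == "optimal" && model$objective$direction == "minimize") {
    res$objective <- -res$objective
  }
  res
}

# Oracle FVA extremum for one reaction at a fraction of the (oracle) optimum,
# implemented by tightening the objective bound exactly as the definition
# states and re-enumerating vertices.
oracle_fva_range <- function(model, reaction, fraction) {
  base <- oracle_fba(model)
  stopifnot(base$status == "optimal")
  k_obj <- match(model$objective$reaction, model$reactions$id)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  lb[k_obj] <- max(lb[k_obj], fraction * base$objective)
  S <- as.matrix(larvaflux::stoichiometric_matrix(model))
  e <- as.numeric(model$reactions$id == reaction)
  hi <- oracle_lp(e, S, lb, ub)
  lo <- oracle_lp(-e, S, lb, ub)
  c(min = -lo$objective, max = hi$objective)
}

# Closed-form bottleneck optimum of a generated larva network: the biomass
# flux is capped per amino acid by uptake / biomass coefficient; under the
# reference conditions carbon and energy are slack (asserted separately),
# so the cap is attained.
analytic_bottleneck <- function(model) {
  spec <- attr(model, "biomass_spec")
  params <- attr(model, "params")
  diet <- reference_diet(params)
  reg <- amino_acid_registry()[seq_len(params$n_amino_acids), ]
  ratios <- vapply(seq_len(nrow(reg)), function(i) {
    ex <- sprintf("EX_%s_e", reg$abbrev[i])
    met <- sprintf("%s_c", reg$abbrev[i])
    diet[[ex]] / spec$coefficients[[met]]
  }, numeric(1))
  chol_ratio <- diet[["EX_chol_e"]] / spec$coefficients[["chol_c"]]
  min(c(ratios, chol_ratio))
}
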