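# Conversion of a fed-diet description into per-larva-per-day exchange
# bounds, and application of those bounds to a model. Uptake convention
# throughout: an uptake limit u on an exchange reaction is encoded as
# lower_bound = -u (negative flux = uptake, positive = secretion).

#' Construct an exchange-bounds object
#'
#' A named vector of uptake limits in mmol/larva/day, keyed by exchange
#' reaction id. Limits are maxima: the optimizer may take up less.
#'
#' @param x Named numeric vector; all values must be >= 0.
#' @return An `exchange_bounds` object.
#' @export
exchange_bounds <- function(x) {
  if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("exchange bounds must be a fully named vector")
  }
  if (any(x < 0)) stop("uptake limits must be >= 0")
  structure(as.numeric(x), names = names(x), class = "exchange_bounds")
}

#' @export
print.exchange_bounds <- function(x, ...) {
  cat(sprintf("<exchange_bounds> %d uptake limit(s), mmol/larva/day\n", length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Mass of an ingredient consumed over the experiment
#'
#' Consumed = applied - residue; the feeding experiments measure both the
#' applied substrate and what is left at the end.
#'
#' @param total_g Applied mass in g, or a list/one-row data frame with
#'   fields `total_g` and `residue_g`.
#' @param residue_g Residual mass in g (ignored when `total_g` is a list).
#' @return Consumed mass in g.
#' @examples
#' consumed_mass(846, 0)      # glucose: fully consumed
#' consumed_mass(1870, 1310)  # egg-white protein: 560 g consumed
#' @export
consumed_mass <- function(total_g, residue_g = NULL) {
  if (is.list(total_g)) {
    residue_g <- total_g$residue_g
    total_g <- total_g$total_g
  }
  if (any(total_g < 0) || any(residue_g < 0)) stop("masses must be >= 0")
  if (any(residue_g > total_g)) stop("residue mass exceeds applied mass")
  total_g - residue_g
}

#' Convert consumed amino-acid masses to per-larva daily uptake rates
#'
#' The unit chain g -> mg/larva/day -> mmol/larva/day under the linear
#' consumption assumption: each larva eats an equal share of the consumed
#' mass on each day. Molar masses default to the amino-acid registry
#' formulas (cystine as the dimer, 240.30 g/mol).
#'
#' @param consumed_aa_mass Named numeric vector, g of each amino acid
#'   consumed over the whole experiment; names as in
#'   [amino_acid_registry()]. May be `NULL` when `profile` and
#'   `consumed_protein_g` are given, in which case consumption is
#'   apportioned by the dietary profile.
#' @param larva_count Number of larvae sharing the substrate.
#' @param duration_days Experiment length in days.
#' @param profile Optional named vector, mg of amino acid per 100 g protein.
#' @param consumed_protein_g Optional total protein mass consumed (g).
#' @param molar_masses Optional named vector of molar masses in g/mol;
#'   defaults to registry formulas.
#' @return An [exchange_bounds()] object keyed by exchange id, with a
#'   `detail` attribute holding the intermediate columns.
#' @export
aa_rates <- function(consumed_aa_mass = NULL, larva_count, duration_days,
                     profile = NULL, consumed_protein_g = NULL,
                     molar_masses = NULL) {
  if (larva_count < 1 || duration_days < 1) {
    stop("larva_count and duration_days must be >= 1")
  }
  if (is.null(consumed_aa_mass)) {
    if (is.null(profile) || is.null(consumed_protein_g)) {
      stop("either consumed_aa_mass or (profile, consumed_protein_g) is required")
    }
    consumed_aa_mass <- consumed_protein_g * profile / sum(profile)
  }
  aas <- names(consumed_aa_mass)
  reg <- amino_acid_registry()
  if (is.null(molar_masses)) {
    molar_masses <- stats::setNames(
      vapply(reg$formula, formula_mass, numeric(1)) * 1000, reg$name)
  }
  missing_mm <- setdiff(aas, names(molar_masses))
  if (length(missing_mm) > 0) {
    stop(sprintf("no molar mass for: %s", paste(missing_mm, collapse = ", ")))
  }
  mg_day <- consumed_aa_mass * 1000 / (larva_count * duration_days)
  mmol_day <- mg_day / molar_masses[aas]  # g/mol == mg/mmol
  bounds <- exchange_bounds(stats::setNames(as.numeric(mmol_day), exchange_id(aas)))
  attr(bounds, "detail") <- data.frame(
    amino_acid = aas,
    consumed_g = as.numeric(consumed_aa_mass),
    mg_per_larva_day = as.numeric(mg_day),
    mmol_per_larva_day = as.numeric(mmol_day),
    stringsAsFactors = FALSE)
  bounds
}

# Exchanges always left open: water, oxygen, carbon dioxide, phosphate,
# sulfate, ammonia -- plus protons, which the package's neutral-formula
# bookkeeping uses as the hydrogen balancing species.
DEFAULT_OPEN_EXCHANGES <- c("EX_h2o_e", "EX_o2_e", "EX_co2_e", "EX_pi_e",
                            "EX_so4_e", "EX_nh3_e", "EX_h_e")

#' Apply diet bounds to a model
#'
#' Sets each listed exchange's lower bound to minus its uptake limit and
#' closes every unlisted exchange to uptake (lower bound 0), except for the
#' whitelisted freely exchanged species. Upper bounds (secretion) are never
#' touched. Applying the same bounds twice is a no-op.
#'
#' @param model A `metabolic_model`.
#' @param bounds An [exchange_bounds()] object.
#' @param open_exchanges Exchange ids left untouched (default: water, O2,
#'   CO2, phosphate, sulfate, ammonia, protons).
#' @return The constrained model.
#' @export
apply_diet <- function(model, bounds,
                       open_exchanges = DEFAULT_OPEN_EXCHANGES) {
  ex_ids <- find_exchange_reactions(model)
  unknown <- setdiff(names(bounds), ex_ids)
  if (length(unknown) > 0) {
    stop(sprintf("diet bounds name non-exchange or missing reaction(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  for (rid in ex_ids) {
    if (rid %in% names(bounds)) {
      model <- set_bounds(model, rid, lower = -unname(bounds[[rid]]))
    } else if (!rid %in% open_exchanges) {
      k <- rxn_index(model, rid)
      model$reactions$lower_bound[k] <- max(model$reactions$lower_bound[k], 0)
    }
  }
  model
}

#' Scale selected uptake limits
#'
#' Multiplies the limits of the targeted exchanges by `factor` (the dietary
#' doubling experiments use factor 2), leaving all others unchanged.
#'
#' @param bounds An [exchange_bounds()] object.
#' @param targets Exchange ids to scale.
#' @param factor Positive scale factor.
#' @return The scaled bounds.
#' @export
scale_uptake <- function(bounds, targets, factor) {
  if (factor <= 0) stop("factor must be > 0")
  unknown <- setdiff(targets, names(bounds))
  if (length(unknown) > 0) {
    stop(sprintf("unknown uptake target(s): %s", paste(unknown, collapse = ", ")))
  }
  out <- unclass(bounds)
  detail <- attr(out, "detail")
  out[targets] <- out[targets] * factor
  res <- exchange_bounds(out)
  attr(res, "detail") <- detail
  res
}
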