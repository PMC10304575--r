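# Construction of a biomass objective reaction from chemical-composition
# assays: macromolecule fractions (g/100 g dry weight), a fatty-acid
# profile (g/100 g fat) and an amino-acid profile (mg/100 g protein) are
# normalized, a cholesterol fraction is grafted in from a donor insect
# model, and everything is converted to mmol per larva dry weight.

#' Construct a composition assay
#'
#' @param macromolecules Named numeric, g per 100 g dry weight, over classes
#'   such as `amino_acids`, `fat`, `starch_glycogen`, `sugars`, `glycerol`,
#'   `water`, `ash`, `carbohydrates_other`.
#' @param fatty_acid_profile Named numeric, g per 100 g fat, keyed by
#'   fatty-acid label (`"C12:0"`, ...).
#' @param amino_acid_profile Named numeric, mg per 100 g protein, keyed by
#'   amino-acid name.
#' @return A `composition_assay` object.
#' @export
composition_assay <- function(macromolecules, fatty_acid_profile,
                              amino_acid_profile) {
  for (x in list(macromolecules, fatty_acid_profile, amino_acid_profile)) {
    if (length(x) == 0 || is.null(names(x))) stop("assay components must be named and non-empty")
    if (any(x < 0, na.rm = TRUE)) stop("assay values must be >= 0")
  }
  structure(list(macromolecules = macromolecules,
                 fatty_acid_profile = fatty_acid_profile,
                 amino_acid_profile = amino_acid_profile),
            class = "composition_assay")
}

#' Default larval composition assay
#'
#' The package's reference larva composition: macromolecule fractions
#' consistent with the validated dry-weight ratios (70% amino acids, 16%
#' fat after cholesterol insertion), the measured fatty-acid profile, and
#' the dietary amino-acid profile standing in for the larval one.
#'
#' @return A [composition_assay()].
#' @export
default_larva_assay <- function() {
  fa <- larva_fatty_acid_profile()
  fa_prof <- stats::setNames(fa$g_per_100g_fat, fa$label)
  fa_prof <- fa_prof[!is.na(fa_prof)]
  aa <- diet_amino_acid_table()
  composition_assay(
    macromolecules = c(amino_acids = 70, fat = 16, starch_glycogen = 6.3,
                       sugars = 4.7, glycerol = 1.0, ash = 2.0, water = 0,
                       carbohydrates_other = 0),
    fatty_acid_profile = fa_prof,
    amino_acid_profile = stats::setNames(aa$mg_per_100g_protein, aa$amino_acid))
}

#' Normalize a composition to mass fractions
#'
#' Drops the excluded classes (typically water, ash and unassayed
#' carbohydrates) and rescales the remainder proportionally to sum to 1.
#' Idempotent: normalizing a normalized map returns it unchanged.
#'
#' @param composition Named numeric masses (any proportional unit), or a
#'   `composition_assay` (its macromolecule map is used).
#' @param excluded Character vector of class names to drop.
#' @return Named numeric mass fractions summing to 1.
#' @examples
#' normalize_composition(c(A = 50, B = 30, water = 20), "water")
#' @export
normalize_composition <- function(composition, excluded = character(0)) {
  if (inherits(composition, "composition_assay")) {
    composition <- composition$macromolecules
  }
  keep <- composition[setdiff(names(composition), excluded)]
  keep <- keep[!is.na(keep)]
  total <- sum(keep)
  if (length(keep) == 0 || total <= 0) {
    stop("nothing left to normalize: all mass excluded or zero")
  }
  keep / total
}

# Chain sets of the two biomass triacylglycerols.
TAG_A_CHAINS <- c("C12:0", "C14:0", "C16:0")
TAG_B_CHAINS <- c("C16:1", "C18:1", "C18:2")

#' Select the biomass triacylglycerol composition
#'
#' The larval storage fat is modeled as two lumped species:
#' TAG A = TAG(12:0/14:0/16:0) and TAG B = TAG(16:1/18:1/18:2), covering
#' the six most abundant measured fatty acids. The declared A:B mass split
#' is 49:51; alternatively the split can be recomputed from the profile as
#' the normalized ratio of summed A-chain to B-chain masses.
#'
#' @param fa_profile Named numeric, g per 100 g fat, containing the six
#'   constituent fatty acids.
#' @param split `"declared"` for the 0.49/0.51 ratio, `"measured"` to
#'   recompute from `fa_profile`, or a numeric pair summing to 1.
#' @return List with `tag_split` (named pair A/B), `tag_a_chains`,
#'   `tag_b_chains`.
#' @export
select_tag_composition <- function(fa_profile, split = "declared") {
  missing <- setdiff(c(TAG_A_CHAINS, TAG_B_CHAINS), names(fa_profile))
  if (length(missing) > 0) {
    stop(sprintf("fatty-acid profile lacks TAG constituent(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (is.character(split)) {
    split <- match.arg(split, c("declared", "measured"))
    tag_split <- if (split == "declared") c(A = 0.49, B = 0.51) else {
      a <- sum(fa_profile[TAG_A_CHAINS])
      b <- sum(fa_profile[TAG_B_CHAINS])
      if (a + b <= 0) stop("TAG constituent masses are all zero")
      c(A = a / (a + b), B = b / (a + b))
    }
  } else {
    if (length(split) != 2 || abs(sum(split)) == 0) stop("numeric split must be a pair")
    tag_split <- c(A = split[1], B = split[2]) / sum(split)
  }
  list(tag_split = tag_split,
       tag_a_chains = TAG_A_CHAINS,
       tag_b_chains = TAG_B_CHAINS)
}

#' Insert an approximated cholesterol fraction
#'
#' Cholesterol is a major membrane constituent but was not assayed; its
#' mass share is approximated from a donor insect biomass function and
#' grafted into the normalized composition, rescaling the assayed classes
#' so the total stays 1.
#'
#' @param fractions Named numeric mass fractions summing to 1.
#' @param donor_ratio Cholesterol-to-total mass ratio in `[0, 0.2]`.
#' @return Fractions including `cholesterol`, summing to 1.
#' @export
approximate_cholesterol <- function(fractions, donor_ratio) {
  if (donor_ratio < 0 || donor_ratio > 0.2) {
    stop("donor cholesterol ratio must lie in [0, 0.2]")
  }
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (donor_ratio == 0) return(fractions)
  out <- fractions * (1 - donor_ratio)
  out["cholesterol"] <- donor_ratio
  out
}

# Lumped TAG formula: glycerol esterified with 3 acyl groups distributed
# equally over the available chains (3 ester bonds release 3 H2O).
tag_formula <- function(chains) {
  reg <- fatty_acid_registry()
  counts <- c(C = 3, H = 8, O = 3)  # glycerol
  per_chain <- 3 / length(chains)
  for (ch in chains) {
    f <- parse_formula(reg$formula[reg$label == ch])
    for (el in names(f)) {
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + per_chain * f[[el]]
    }
  }
  counts["H"] <- counts[["H"]] - 6
  counts["O"] <- counts[["O"]] - 3
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("TAG chain set does not yield an integer formula")
  }
  paste0(names(counts), ifelse(round(counts) == 1, "", round(counts)), collapse = "")
}

# Metabolite ids and formulas of the biomass precursor pools.
biomass_pool_registry <- function(tag_a_chains = TAG_A_CHAINS,
                                  tag_b_chains = TAG_B_CHAINS) {
  data.frame(
    class = c("starch_glycogen", "sugars", "glycerol", "cholesterol",
              "tag_a", "tag_b"),
    metabolite = c("glycogen_c", "tre_c", "glycerol_c", "chol_c",
                   "tag_a_c", "tag_b_c"),
    formula = c("C6H10O5", "C12H22O11", "C3H8O3", "C27H46O",
                tag_formula(tag_a_chains), tag_formula(tag_b_chains)),
    stringsAsFactors = FALSE)
}

#' Build a biomass specification from a composition assay
#'
#' Normalizes the assay (dropping `excluded`), grafts in the donor
#' cholesterol fraction, splits the fat class over the two TAG species,
#' expands the amino-acid class over the profile, and converts every mass
#' fraction to mmol per larva: coefficient = fraction x dry weight / molar
#' mass. The coefficients reconstruct the dry weight exactly:
#' sum(coefficient x molar mass) = larva_dry_weight.
#'
#' @param assay A [composition_assay()].
#' @param larva_dry_weight Larva dry weight in g. The default derives from
#'   the measured 0.028 g wet weight under the 70%-moisture convention.
#' @param tag_split Passed to [select_tag_composition()].
#' @param cholesterol_fraction Donor cholesterol mass ratio.
#' @param excluded Macromolecule classes omitted from the biomass.
#' @param tag_a_chains,tag_b_chains Fatty-acid labels esterified in the two
#'   TAG species; override the canonical sets when modeling a restricted
#'   fatty-acid repertoire. An empty group forfeits its mass share to the
#'   other group.
#' @return An object of class `biomass_spec` with fields
#'   `normalized_mass_fractions`, `tag_split`, `cholesterol_fraction`,
#'   `coefficients` (named mmol per larva, by metabolite id),
#'   `molar_masses` (g/mmol) and `larva_dry_weight`.
#' @export
build_biomass_spec <- function(assay,
                               larva_dry_weight = 0.3 * 0.028,
                               tag_split = "declared",
                               cholesterol_fraction = 0.02,
                               excluded = c("water", "ash", "carbohydrates_other"),
                               tag_a_chains = TAG_A_CHAINS,
                               tag_b_chains = TAG_B_CHAINS) {
  stopifnot(inherits(assay, "composition_assay"))
  if (larva_dry_weight <= 0) stop("larva_dry_weight must be > 0")
  fractions <- normalize_composition(assay, excluded)
  fractions <- approximate_cholesterol(fractions, cholesterol_fraction)
  canonical <- setequal(tag_a_chains, TAG_A_CHAINS) &&
    setequal(tag_b_chains, TAG_B_CHAINS)
  if (canonical) {
    tags <- select_tag_composition(assay$fatty_acid_profile, split = tag_split)
  } else {
    if (length(tag_a_chains) == 0 && length(tag_b_chains) == 0) {
      stop("at least one TAG chain group must be non-empty")
    }
    missing <- setdiff(c(tag_a_chains, tag_b_chains),
                       names(assay$fatty_acid_profile))
    if (length(missing) > 0) {
      stop(sprintf("fatty-acid profile lacks TAG constituent(s): %s",
                   paste(missing, collapse = ", ")))
    }
    split <- if (is.numeric(tag_split)) tag_split / sum(tag_split) else c(0.49, 0.51)
    split <- c(A = split[[1]], B = split[[2]])
    if (length(tag_a_chains) == 0) split <- c(A = 0, B = 1)
    if (length(tag_b_chains) == 0) split <- c(A = 1, B = 0)
    tags <- list(tag_split = split, tag_a_chains = tag_a_chains,
                 tag_b_chains = tag_b_chains)
  }

  pools <- biomass_pool_registry(
    if (length(tags$tag_a_chains) > 0) tags$tag_a_chains else TAG_A_CHAINS,
    if (length(tags$tag_b_chains) > 0) tags$tag_b_chains else TAG_B_CHAINS)
  aa_reg <- amino_acid_registry()
  coefs <- numeric(0)
  masses <- numeric(0)

  for (cls in names(fractions)) {
    frac <- fractions[[cls]]
    if (frac == 0) next
    if (cls == "amino_acids") {
      prof <- assay$amino_acid_profile
      unknown <- setdiff(names(prof), aa_reg$name)
      if (length(unknown) > 0) {
        stop(sprintf("amino-acid profile names not in registry: %s",
                     paste(unknown, collapse = ", ")))
      }
      share <- prof / sum(prof)
      for (aa in names(prof)) {
        row <- aa_reg[aa_reg$name == aa, ]
        met <- sprintf("%s_c", row$abbrev)
        masses[met] <- formula_mass(row$formula)
        coefs[met] <- frac * share[[aa]] * larva_dry_weight / masses[met]
      }
    } else if (cls == "fat") {
      for (g in c("A", "B")) {
        if (tags$tag_split[[g]] == 0) next
        met <- if (g == "A") "tag_a_c" else "tag_b_c"
        masses[met] <- formula_mass(pools$formula[pools$metabolite == met])
        coefs[met] <- frac * tags$tag_split[[g]] * larva_dry_weight / masses[met]
      }
    } else {
      row <- pools[pools$class == cls, ]
      if (nrow(row) == 0) {
        stop(sprintf("no biomass precursor pool defined for class '%s'", cls))
      }
      masses[row$metabolite] <- formula_mass(row$formula)
      coefs[row$metabolite] <- frac * larva_dry_weight / masses[row$metabolite]
    }
  }
  structure(list(normalized_mass_fractions = fractions,
                 tag_split = tags$tag_split,
                 cholesterol_fraction = cholesterol_fraction,
                 coefficients = coefs,
                 molar_masses = masses,
                 larva_dry_weight = larva_dry_weight),
            class = "biomass_spec")
}

#' Assemble the biomass reaction from a specification
#'
#' Substrate coefficients are the negated mmol-per-larva precursor demands;
#' the reaction produces one unit of the `biomass` pseudo-metabolite, so
#' its flux is the growth rate in larva dry weights per day.
#'
#' @param spec A `biomass_spec`.
#' @param molar_masses Optional named vector (g/mmol) overriding the
#'   spec's; every coefficient's metabolite must be covered.
#' @param biomass_metabolite Id of the produced pseudo-metabolite.
#' @return List describing the reaction: `id`, `name`, `stoichiometry`,
#'   `lower_bound`, `upper_bound`.
#' @export
assemble_biomass_reaction <- function(spec, molar_masses = NULL,
                                      biomass_metabolite = "biomass_c") {
  stopifnot(inherits(spec, "biomass_spec"))
  coefs <- spec$coefficients
  if (!is.null(molar_masses)) {
    missing <- setdiff(names(coefs), names(molar_masses))
    if (length(missing) > 0) {
      stop(sprintf("no molar mass for biomass metabolite(s): %s",
                   paste(missing, collapse = ", ")))
    }
  }
  st <- c(stats::setNames(-as.numeric(coefs), names(coefs)),
          stats::setNames(1, biomass_metabolite))
  list(id = "BIOMASS", name = "biomass assembly (larva dry weight)",
       stoichiometry = st, lower_bound = 0, upper_bound = DEFAULT_BOUND)
}

#' Fatty-acid profile bookkeeping
#'
#' Saturation-class sums over a measured fatty-acid profile: total
#' saturated (C12:0 + C14:0 + C16:0 + C18:0), unsaturated
#' (C14:1 + C16:1 + C18:1 + C18:2), mono- and polyunsaturated shares, and
#' the joint coverage of the six TAG-modeled species. Rounded figures use
#' round-half-away-from-zero integer percent.
#'
#' @param profile Named numeric, g per 100 g fat; defaults to the measured
#'   larval profile.
#' @return List of raw sums (`*_g`) and rounded percentages (`*_pct`).
#' @export
fatty_acid_bookkeeping <- function(profile = NULL) {
  if (is.null(profile)) {
    fa <- larva_fatty_acid_profile()
    profile <- stats::setNames(fa$g_per_100g_fat, fa$label)
    profile <- profile[!is.na(profile)]
  }
  grab <- function(labels) sum(profile[intersect(labels, names(profile))])
  sat <- grab(c("C12:0", "C14:0", "C16:0", "C18:0"))
  unsat <- grab(c("C14:1", "C16:1", "C18:1", "C18:2"))
  mono <- grab(c("C14:1", "C16:1", "C18:1"))
  poly <- grab("C18:2")
  modeled <- grab(c(TAG_A_CHAINS, TAG_B_CHAINS))
  list(saturated_g = sat, unsaturated_g = unsat,
       monounsaturated_g = mono, polyunsaturated_g = poly,
       modeled_coverage_g = modeled,
       saturated_pct = round_half_away(sat),
       unsaturated_pct = round_half_away(unsat),
       monounsaturated_pct = round_half_away(mono),
       polyunsaturated_pct = round_half_away(poly),
       lauric_pct = round_half_away(grab("C12:0")),
       oleic_pct = round_half_away(grab("C18:1")),
       linoleic_pct = round_half_away(grab("C18:2")))
}
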