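# Reference data: the dietary and composition assay tables of the
# black-soldier-fly larva study this package operates on, plus the compound
# registry (formulas, short ids) shared by the diet converter, the biomass
# builder and the synthetic network generator. Molar masses are always
# derived from the formulas via formula_mass(), never typed in twice.

#' Amino-acid compound registry
#'
#' The twenty dietary amino-acid species with short ids (used in exchange
#' and transport reaction names), neutral Hill formulas, and an
#' essential/non-essential flag. The sulfur amino acid is carried as
#' cystine (the dimer measured in the dietary assay), so its molar mass is
#' the dimer's 240.30 g/mol.
#'
#' @return `data.frame` with columns `name`, `abbrev`, `formula`, `essential`.
#' @export
amino_acid_registry <- function() {
  tab <- read.csv(text = "name,abbrev,formula,essential
Lysine,lys,C6H14N2O2,TRUE
Methionine,met,C5H11NO2S,TRUE
Cystine,cys,C6H12N2O4S2,FALSE
Aspartate,asp,C4H7NO4,FALSE
Asparagine,asn,C4H8N2O3,FALSE
Threonine,thr,C4H9NO3,TRUE
Serine,ser,C3H7NO3,FALSE
Glutamate,glu,C5H9NO4,FALSE
Glutamine,gln,C5H10N2O3,FALSE
Proline,pro,C5H9NO2,FALSE
Glycine,gly,C2H5NO2,FALSE
Alanine,ala,C3H7NO2,FALSE
Valine,val,C5H11NO2,TRUE
Isoleucine,ile,C6H13NO2,TRUE
Leucine,leu,C6H13NO2,TRUE
Tyrosine,tyr,C9H11NO3,FALSE
Phenylalanine,phe,C9H11NO2,TRUE
Histidine,his,C6H9N3O2,TRUE
Arginine,arg,C6H14N4O2,TRUE
Tryptophan,trp,C11H12N2O2,TRUE
", stringsAsFactors = FALSE)
  tab
}

#' Essential amino acid names
#'
#' The classical animal essential set (Lys, Met, Thr, Val, Ile, Leu, Phe,
#' His, Arg, Trp); used as the default target set of the doubled-EAA
#' perturbation and configurable everywhere it is consumed.
#'
#' @return Character vector of amino-acid names.
#' @export
essential_amino_acids <- function() {
  reg <- amino_acid_registry()
  reg$name[reg$essential]
}

#' Non-amino-acid dietary compound registry
#'
#' @return `data.frame` with `name`, `abbrev`, `formula` for glucose and
#'   cholesterol, the two non-amino-acid dietary carbon sources.
#' @export
dietary_compound_registry <- function() {
  data.frame(
    name = c("Glucose", "Cholesterol"),
    abbrev = c("glc", "chol"),
    formula = c("C6H12O6", "C27H46O"),
    stringsAsFactors = FALSE)
}

#' Canonical exchange reaction id for a dietary compound
#'
#' Maps a compound name (e.g. `"Valine"`, `"Glucose"`) to the exchange
#' reaction id convention used by the synthetic networks: `EX_<abbrev>_e`.
#'
#' @param name Compound name as it appears in the registries.
#' @return Exchange reaction id string.
#' @examples
#' exchange_id("Lysine")  # "EX_lys_e"
#' @export
exchange_id <- function(name) {
  reg <- rbind(amino_acid_registry()[, c("name", "abbrev")],
               dietary_compound_registry()[, c("name", "abbrev")])
  k <- match(name, reg$name)
  if (anyNA(k)) {
    stop(sprintf("unknown dietary compound(s): %s",
                 paste(name[is.na(k)], collapse = ", ")))
  }
  sprintf("EX_%s_e", reg$abbrev[k])
}

#' Dietary amino-acid profile and derived per-larva transport rates
#'
#' The egg-white-protein amino-acid profile of the feeding experiment: the
#' profile (mg per 100 g protein), the amino-acid mass consumed over the
#' 9-day experiment (g), and its conversion to per-larva daily rates
#' (mg/larva/day and mmol/larva/day). The printed per-larva columns are the
#' authoritative diet description; [aa_rates()] reproduces the mmol column
#' from the mg column and the registry molar masses.
#'
#' @return `data.frame` with columns `amino_acid`, `mg_per_100g_protein`,
#'   `consumed_g`, `mg_per_larva_day`, `mmol_per_larva_day`.
#' @export
diet_amino_acid_table <- function() {
  read.csv(text = "amino_acid,mg_per_100g_protein,consumed_g,mg_per_larva_day,mmol_per_larva_day
Lysine,6000,85.272,1.769,0.012
Methionine,3500,50.116,1.039,0.007
Cystine,2500,36.465,0.756,0.003
Aspartate,4800,48.62,1.008,0.008
Asparagine,4800,48.62,1.008,0.008
Threonine,4300,62.832,1.303,0.011
Serine,6400,93.687,1.943,0.018
Glutamate,6150,62.271,1.292,0.009
Glutamine,6150,62.271,1.292,0.009
Proline,3600,52.921,1.098,0.010
Glycine,3300,47.872,0.993,0.013
Alanine,5800,84.898,1.761,0.020
Valine,6500,95.183,1.974,0.017
Isoleucine,5100,74.239,1.540,0.012
Leucine,8000,117.062,2.428,0.019
Tyrosine,3700,54.604,1.133,0.006
Phenylalanine,5500,78.914,1.637,0.010
Histidine,2200,32.164,0.667,0.004
Arginine,5400,79.475,1.648,0.009
Tryptophan,1500,23.001,0.477,0.002
", stringsAsFactors = FALSE)
}

#' Fed-diet ingredient masses of the rearing experiment
#'
#' Total and residual ingredient masses over the 9-day feeding window:
#' glucose was consumed completely, egg-white protein and water left
#' residue.
#'
#' @return `data.frame` with `ingredient`, `percent`, `g_per_100g`,
#'   `total_g`, `residue_g`.
#' @export
diet_ingredient_table <- function() {
  data.frame(
    ingredient = c("Glucose", "Egg White Protein", "Water"),
    percent = c(10, 20, 70),
    g_per_100g = c(10.58, 23.38, 66.05),
    total_g = c(846, 1870, 5284),
    residue_g = c(0, 1310, 4890),
    stringsAsFactors = FALSE)
}

#' Larval fatty-acid profile (g per 100 g fat)
#'
#' The measured fatty-acid composition of the larvae. `modeled` marks the
#' six species carried into the biomass triacylglycerols; entries reported
#' below the 0.10 quantification limit are `NA`. Stearate (C18:0) is
#' synthesized by the metabolic network but not part of the biomass TAGs.
#'
#' @return `data.frame` with `fatty_acid`, `label`, `g_per_100g_fat`,
#'   `modeled`, `saturated`.
#' @export
larva_fatty_acid_profile <- function() {
  data.frame(
    fatty_acid = c("Caprylic acid", "Lauric acid", "Myristic acid",
                   "Myristoleic acid", "Palmitic acid", "Palmitoleic acid",
                   "Stearic acid", "Oleic acid", "Linoleic acid",
                   "Linolenic acid, alpha", "Linolenic acid, gamma",
                   "Eicosapentaenoic acid", "Docosahexaenoic acid"),
    label = c("C8:0", "C12:0", "C14:0", "C14:1", "C16:0", "C16:1",
              "C18:0", "C18:1", "C18:2", "C18:3a", "C18:3g", "C20:5", "C22:6"),
    g_per_100g_fat = c(0.13, 29.4, 5.75, 0.73, 10.45, 5.69, 3.5,
                       21.05, 19.8, 0.48, NA, NA, NA),
    modeled = c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE,
                FALSE, FALSE, FALSE, FALSE),
    saturated = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                  FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Fatty-acid species registry
#'
#' The seven fatty acids whose synthesis the models resolve, with Hill
#' formulas and the lumped-pathway cost coefficients used by the synthetic
#' network generator: acetyl-CoA units (`acetyl_units`), ATP for the
#' carboxylation/condensation steps (`atp`), NADPH for reduction (`nadph`),
#' molecular oxygen (`o2`) and reduced cytochrome b5 (`cytb5`) for the
#' desaturations. Oleate and linoleate synthesis is gated by the
#' cytochrome-b5 reductase recharge reaction.
#'
#' @return `data.frame` with `label`, `id`, `name`, `formula`,
#'   `acetyl_units`, `atp`, `nadph`, `o2`, `cytb5`, `tag_group` (`"A"` for
#'   the saturated TAG, `"B"` for the unsaturated TAG, `NA` for C18:0).
#' @export
fatty_acid_registry <- function() {
  data.frame(
    label = c("C12:0", "C14:0", "C16:0", "C16:1", "C18:0", "C18:1", "C18:2"),
    id = c("c120", "c140", "c160", "c161", "c180", "c181", "c182"),
    name = c("laurate", "myristate", "palmitate", "palmitoleate",
             "stearate", "oleate", "linoleate"),
    formula = c("C12H24O2", "C14H28O2", "C16H32O2", "C16H30O2",
                "C18H36O2", "C18H34O2", "C18H32O2"),
    acetyl_units = c(6, 7, 8, 8, 9, 9, 9),
    atp = c(5, 6, 7, 7, 8, 8, 8),
    nadph = c(10, 12, 14, 15, 16, 16, 16),
    o2 = c(0, 0, 0, 1, 0, 1, 2),
    cytb5 = c(0, 0, 0, 0, 0, 2, 4),
    tag_group = c("A", "A", "A", "B", NA, "B", "B"),
    stringsAsFactors = FALSE)
}

#' Round half away from zero
#'
#' Display rounding used for reported percentages (49/28/20-style headline
#' figures), where the usual banker's rounding of `round()` would
#' under-report `x.5` values.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
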