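# Deterministic generator of small larva-like metabolic networks. The
# networks carry the qualitative architecture of the larval reconstruction
# -- dietary amino-acid/glucose/cholesterol exchanges and transports, a
# lumped acetyl-CoA carbon backbone, one lumped mass-balanced synthesis
# reaction per fatty acid (cytochrome-b5-gated desaturations), two lumped
# TAG-assembly reactions, and a composition-derived biomass reaction -- at
# a scale where the FBA optimum has a closed analytic form: the biomass
# precursor bottleneck min_i(uptake_i / coefficient_i), with carbon and
# energy demands verifiably slack under the reference diet.
#
# Randomness is cosmetic only (ordering and optional decoy reactions); the
# core topology and all coefficients are deterministic, so analytic optima
# stay derivable for any seed.

#' Parameters for the synthetic network generator
#'
#' @param n_amino_acids How many registry amino acids to include (1-20,
#'   taken in registry order; the default 20 is the full dietary set).
#' @param fatty_acid_set Fatty-acid labels to resolve (subset of the seven
#'   in [fatty_acid_registry()]).
#' @param tag_split Mass split of biomass fat over TAG A and TAG B
#'   (default the declared 0.49/0.51).
#' @param include_glucose Include glucose exchange/transport and the
#'   glucose-derived carbon backbone.
#' @param biomass `"auto"` to derive the biomass reaction from
#'   [default_larva_assay()], or a prebuilt `biomass_spec`.
#' @param seed Integer seed driving the cosmetic shuffling.
#' @param n_decoys Number of decoy dead-end reactions (balanced isomerase
#'   stubs) mixed in, as real reconstructions carry them.
#' @param larva_count,duration_days Reference feeding-experiment scale used
#'   by [reference_diet()]; the larva count defaults to the value implied
#'   by the per-larva amino-acid rate table.
#' @param larva_dry_weight Larva dry weight in g.
#' @param cholesterol_fraction Donor cholesterol mass share of the biomass.
#' @param cholesterol_uptake Dietary cholesterol availability in
#'   mmol/larva/day (sterols are assumed non-limiting).
#' @return A `synthetic_network_params` list.
#' @export
synthetic_network_params <- function(n_amino_acids = 20,
                                     fatty_acid_set = fatty_acid_registry()$label,
                                     tag_split = c(0.49, 0.51),
                                     include_glucose = TRUE,
                                     biomass = "auto",
                                     seed = 7L,
                                     n_decoys = 2,
                                     larva_count = implied_larva_count(),
                                     duration_days = 9,
                                     larva_dry_weight = 0.3 * 0.028,
                                     cholesterol_fraction = 0.02,
                                     cholesterol_uptake = 0.01) {
  if (abs(sum(tag_split) - 1) > 1e-9) stop("tag_split must sum to 1")
  if (length(fatty_acid_set) == 0) stop("fatty_acid_set must be non-empty")
  unknown <- setdiff(fatty_acid_set, fatty_acid_registry()$label)
  if (length(unknown) > 0) {
    stop(sprintf("unknown fatty acid(s): %s", paste(unknown, collapse = ", ")))
  }
  if (n_amino_acids < 1 || n_amino_acids > nrow(amino_acid_registry())) {
    stop("n_amino_acids must be between 1 and the registry size")
  }
  structure(list(n_amino_acids = as.integer(n_amino_acids),
                 fatty_acid_set = fatty_acid_set,
                 tag_split = tag_split,
                 include_glucose = isTRUE(include_glucose),
                 biomass = biomass,
                 seed = as.integer(seed),
                 n_decoys = as.integer(n_decoys),
                 larva_count = larva_count,
                 duration_days = duration_days,
                 larva_dry_weight = larva_dry_weight,
                 cholesterol_fraction = cholesterol_fraction,
                 cholesterol_uptake = cholesterol_uptake),
            class = "synthetic_network_params")
}

# Larva count implied by the per-larva amino-acid rate table: total
# consumed mass / (duration x per-larva daily rate), consistent across all
# twenty amino acids to ~0.05%.
implied_larva_count <- function(tab = diet_amino_acid_table(), duration_days = 9) {
  round(stats::median(tab$consumed_g * 1000 /
                        (duration_days * tab$mg_per_larva_day)))
}

#' Reference diet exchange bounds for synthetic networks
#'
#' The per-larva daily uptake limits of the feeding experiment: the twenty
#' printed amino-acid rates (mmol/larva/day), a glucose rate derived from
#' the 846 g consumed over 9 days under linear consumption, and a
#' non-limiting cholesterol allowance.
#'
#' @param params A [synthetic_network_params()].
#' @return An [exchange_bounds()] object.
#' @export
reference_diet <- function(params = synthetic_network_params()) {
  aa_tab <- diet_amino_acid_table()
  aa_tab <- aa_tab[seq_len(params$n_amino_acids), ]
  bounds <- stats::setNames(aa_tab$mmol_per_larva_day,
                            exchange_id(aa_tab$amino_acid))
  if (params$include_glucose) {
    glc_total <- consumed_mass(diet_ingredient_table()[1, c("total_g", "residue_g")])
    bounds["EX_glc_e"] <- glc_total / formula_mass("C6H12O6") /
      (params$larva_count * params$duration_days)
  }
  bounds["EX_chol_e"] <- params$cholesterol_uptake
  exchange_bounds(bounds)
}

# Formula table for the currency and pool species of the generated
# networks. cytb5 carries the heme-b formula; its reduced form is +1 H.
SYNTH_SPECIES <- c(
  h2o = "H2O", h = "H", o2 = "O2", co2 = "CO2", nh3 = "NH3",
  pi = "H3PO4", so4 = "O4S",
  atp = "C10H16N5O13P3", adp = "C10H15N5O10P2",
  nadph = "C21H30N7O17P3", nadp = "C21H29N7O17P3",
  coa = "C21H36N7O16P3S", accoa = "C23H38N7O17P3S",
  cytb5_ox = "C34H32FeN4O4", cytb5_red = "C34H33FeN4O4",
  glc = "C6H12O6", chol = "C27H46O", glycerol = "C3H8O3",
  glycogen = "C6H10O5", tre = "C12H22O11")

# Balance a reaction's H and O by adjusting water and proton coefficients
# (the standard currency species of neutral-formula bookkeeping). Any
# imbalance in other elements is a generator bug and errors out.
balance_with_water <- function(st, formulas, water_id, proton_id, rid) {
  total <- sum_elements(unname(st), formulas[names(st)])
  if (is.null(total)) stop(sprintf("reaction '%s': unweighable formula", rid))
  other <- setdiff(names(total)[abs(total) > 1e-9], c("H", "O"))
  if (length(other) > 0) {
    stop(sprintf("reaction '%s' cannot be balanced: %s imbalance", rid,
                 paste(other, collapse = ", ")))
  }
  o_imb <- if ("O" %in% names(total)) total[["O"]] else 0
  if (abs(o_imb) > 1e-9) {
    st[water_id] <- (if (water_id %in% names(st)) st[[water_id]] else 0) - o_imb
  }
  total <- sum_elements(unname(st), formulas[names(st)])
  h_imb <- if ("H" %in% names(total)) total[["H"]] else 0
  if (abs(h_imb) > 1e-9) {
    st[proton_id] <- (if (proton_id %in% names(st)) st[[proton_id]] else 0) - h_imb
  }
  st[abs(st) > 1e-12]
}

#' Generate a larva-like synthetic metabolic network
#'
#' Builds a three-compartment (extracellular/cytosol/mitochondrion)
#' stoichiometric model: dietary exchanges and transports for the selected
#' amino acids, glucose and cholesterol; freely exchanged small species
#' (water, O2, CO2, ammonia, phosphate, sulfate, protons); lumped
#' glycolysis+pyruvate-dehydrogenase, mitochondrial respiration, and
#' pentose-phosphate NADPH supply; one mass-balanced lumped synthesis
#' reaction per fatty acid (desaturations gated by the cytochrome-b5
#' reductase recharge); two TAG-assembly reactions; per-amino-acid
#' catabolic lumps; a composition-derived biomass reaction; demand drains
#' for biomass and each fatty acid; and optional balanced decoy dead ends.
#' Reference-diet bounds are applied, so the returned model is feasible
#' with a positive growth optimum out of the box. Identical parameters
#' (including seed) give byte-identical models.
#'
#' @param params A [synthetic_network_params()].
#' @return A `metabolic_model` with attributes `biomass_spec` and `params`.
#' @export
generate_network <- function(params = synthetic_network_params()) {
  stopifnot(inherits(params, "synthetic_network_params"))
  aa_reg <- amino_acid_registry()[seq_len(params$n_amino_acids), ]
  fa_reg <- fatty_acid_registry()
  fa_reg <- fa_reg[fa_reg$label %in% params$fatty_acid_set, ]

  chains_a <- intersect(TAG_A_CHAINS, fa_reg$label)
  chains_b <- intersect(TAG_B_CHAINS, fa_reg$label)
  if (length(chains_a) == 0 && length(chains_b) == 0) {
    stop(paste("infeasible parameters: no TAG-forming fatty acid available;",
               "biomass fat cannot be assembled"))
  }
  if (!params$include_glucose) {
    stop(paste("infeasible parameters: without glucose the glycogen, sugar,",
               "glycerol and NADPH biomass precursors have no source"))
  }

  # --- biomass specification -----------------------------------------------
  spec <- if (inherits(params$biomass, "biomass_spec")) params$biomass else {
    assay <- default_larva_assay()
    assay$amino_acid_profile <- assay$amino_acid_profile[aa_reg$name]
    build_biomass_spec(assay,
                       larva_dry_weight = params$larva_dry_weight,
                       tag_split = params$tag_split,
                       cholesterol_fraction = params$cholesterol_fraction,
                       tag_a_chains = chains_a, tag_b_chains = chains_b)
  }

  # --- metabolite table ----------------------------------------------------
  mets <- empty_metabolite_frame()
  add_met <- function(id, name, comp, formula = NA_character_) {
    mets[nrow(mets) + 1L, ] <<- list(id, name, comp, formula, NA_integer_)
  }
  for (sp in c("h2o", "h", "o2", "co2", "nh3", "pi", "so4")) {
    add_met(paste0(sp, "_e"), sp, "e", SYNTH_SPECIES[[sp]])
    add_met(paste0(sp, "_c"), sp, "c", SYNTH_SPECIES[[sp]])
  }
  for (sp in c("h2o", "h", "o2", "co2", "pi")) {
    add_met(paste0(sp, "_m"), sp, "m", SYNTH_SPECIES[[sp]])
  }
  for (i in seq_len(nrow(aa_reg))) {
    add_met(paste0(aa_reg$abbrev[i], "_e"), aa_reg$name[i], "e", aa_reg$formula[i])
    add_met(paste0(aa_reg$abbrev[i], "_c"), aa_reg$name[i], "c", aa_reg$formula[i])
  }
  add_met("glc_e", "Glucose", "e", SYNTH_SPECIES[["glc"]])
  add_met("glc_c", "Glucose", "c", SYNTH_SPECIES[["glc"]])
  add_met("chol_e", "Cholesterol", "e", SYNTH_SPECIES[["chol"]])
  add_met("chol_c", "Cholesterol", "c", SYNTH_SPECIES[["chol"]])
  for (sp in c("atp", "adp", "nadph", "nadp", "coa", "accoa",
               "cytb5_ox", "cytb5_red", "glycerol", "glycogen", "tre")) {
    add_met(paste0(sp, "_c"), sp, "c", SYNTH_SPECIES[[sp]])
  }
  for (sp in c("atp", "adp", "coa", "accoa")) {
    add_met(paste0(sp, "_m"), sp, "m", SYNTH_SPECIES[[sp]])
  }
  for (i in seq_len(nrow(fa_reg))) {
    add_met(paste0(fa_reg$id[i], "_c"), fa_reg$name[i], "c", fa_reg$formula[i])
  }
  if (length(chains_a) > 0) {
    add_met("tag_a_c", "TAG (12:0/14:0/16:0)", "c", tag_formula(chains_a))
  }
  if (length(chains_b) > 0) {
    add_met("tag_b_c", "TAG (16:1/18:1/18:2)", "c", tag_formula(chains_b))
  }
  add_met("biomass_c", "larva biomass (dry weight)", "c")

  formulas <- stats::setNames(mets$formula, mets$id)

  # --- reactions -----------------------------------------------------------
  rxns <- empty_reaction_frame()
  stoich <- list()
  add_rxn <- function(id, name, st, lb = 0, ub = DEFAULT_BOUND,
                      subsystem = "", balance = TRUE, comp = "c") {
    if (balance) {
      st <- balance_with_water(st, formulas, paste0("h2o_", comp),
                               paste0("h_", comp), id)
    }
    rxns[nrow(rxns) + 1L, ] <<- list(id, name, lb, ub, "", subsystem)
    stoich[[id]] <<- st
  }

  # Exchanges and transports.
  for (sp in c("h2o", "o2", "co2", "nh3", "pi", "so4", "h")) {
    e <- paste0(sp, "_e"); cc <- paste0(sp, "_c")
    add_rxn(paste0("EX_", e), paste(sp, "exchange"),
            stats::setNames(-1, e), lb = -DEFAULT_BOUND,
            subsystem = "exchange", balance = FALSE)
    add_rxn(paste0("t_", sp), paste(sp, "diffusion"),
            stats::setNames(c(-1, 1), c(e, cc)), lb = -DEFAULT_BOUND,
            subsystem = "transport", balance = FALSE)
  }
  for (i in seq_len(nrow(aa_reg))) {
    ab <- aa_reg$abbrev[i]
    add_rxn(paste0("EX_", ab, "_e"), paste(aa_reg$name[i], "exchange"),
            stats::setNames(-1, paste0(ab, "_e")), lb = 0,
            subsystem = "exchange", balance = FALSE)
    add_rxn(paste0("t_", ab), paste(aa_reg$name[i], "uptake transport"),
            stats::setNames(c(-1, 1), paste0(ab, c("_e", "_c"))),
            subsystem = "transport", balance = FALSE)
  }
  for (sp in c("glc", "chol")) {
    add_rxn(paste0("EX_", sp, "_e"), paste(sp, "exchange"),
            stats::setNames(-1, paste0(sp, "_e")), lb = 0,
            subsystem = "exchange", balance = FALSE)
    add_rxn(paste0("t_", sp), paste(sp, "uptake transport"),
            stats::setNames(c(-1, 1), paste0(sp, c("_e", "_c"))),
            subsystem = "transport", balance = FALSE)
  }
  # Mitochondrial shuttles.
  for (sp in c("h2o", "h", "o2", "co2", "pi")) {
    add_rxn(paste0("t_", sp, "_m"), paste(sp, "mitochondrial transport"),
            stats::setNames(c(-1, 1), paste0(sp, c("_c", "_m"))),
            lb = -DEFAULT_BOUND, subsystem = "transport", balance = FALSE)
  }
  add_rxn("t_accoa_m", "acetyl-CoA mitochondrial import (lumped shuttle)",
          c(accoa_c = -1, accoa_m = 1), subsystem = "transport", balance = FALSE)
  add_rxn("t_coa_m", "CoA mitochondrial shuttle",
          c(coa_c = -1, coa_m = 1), lb = -DEFAULT_BOUND,
          subsystem = "transport", balance = FALSE)
  add_rxn("ANT", "adenine nucleotide translocase",
          c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
          subsystem = "transport", balance = FALSE)

  # Carbon backbone.
  add_rxn("ACCOA_SYN", "glycolysis + pyruvate dehydrogenase (lumped)",
          c(glc_c = -1, coa_c = -2, adp_c = -2, pi_c = -2,
            accoa_c = 2, co2_c = 2, atp_c = 2),
          subsystem = "central carbon")
  add_rxn("RESP", "acetyl-CoA oxidation + oxidative phosphorylation (lumped)",
          c(accoa_m = -1, o2_m = -2, adp_m = -10, pi_m = -10,
            co2_m = 2, coa_m = 1, atp_m = 10),
          subsystem = "central carbon", comp = "m")
  add_rxn("PPP", "oxidative pentose phosphate NADPH supply (lumped)",
          c(glc_c = -1, nadp_c = -12, co2_c = 6, nadph_c = 12),
          subsystem = "central carbon")
  add_rxn("CYTB5R", "cytochrome-b5 reductase",
          c(nadph_c = -1, cytb5_ox_c = -2, nadp_c = 1, cytb5_red_c = 2),
          subsystem = "lipid synthesis")

  # Lumped fatty-acid synthesis (acyl-CoA synthesis + thioester hydrolysis).
  for (i in seq_len(nrow(fa_reg))) {
    r <- fa_reg[i, ]
    if (r$cytb5 > 0 && !"CYTB5R" %in% rxns$id) {
      stop(sprintf("infeasible parameters: %s requires cytochrome b5", r$label))
    }
    st <- c(-r$acetyl_units, -r$nadph, -r$atp,
            1, r$acetyl_units, r$nadph, r$atp, r$atp)
    names(st) <- c("accoa_c", "nadph_c", "atp_c",
                   paste0(r$id, "_c"), "coa_c", "nadp_c", "adp_c", "pi_c")
    if (r$o2 > 0) st["o2_c"] <- -r$o2
    if (r$cytb5 > 0) {
      st["cytb5_red_c"] <- -r$cytb5
      st["cytb5_ox_c"] <- r$cytb5
    }
    add_rxn(paste0("FAS_", r$id), sprintf("%s synthesis (lumped, %s)",
                                          r$name, r$label),
            st, subsystem = "lipid synthesis")
  }

  # Glycerol, glycogen, trehalose pools.
  add_rxn("GLYC_SYN", "glycerol synthesis (lumped)",
          c(glc_c = -1, nadph_c = -2, glycerol_c = 2, nadp_c = 2),
          subsystem = "carbohydrate pools")
  add_rxn("GLYCOGEN_SYN", "glycogen unit synthesis (lumped)",
          c(glc_c = -1, atp_c = -1, glycogen_c = 1, adp_c = 1, pi_c = 1),
          subsystem = "carbohydrate pools")
  add_rxn("TRE_SYN", "trehalose synthesis (lumped)",
          c(glc_c = -2, atp_c = -1, tre_c = 1, adp_c = 1, pi_c = 1),
          subsystem = "carbohydrate pools")

  # TAG assembly (lumped glycerolipid esterification).
  add_tag <- function(tag_id, chains, label) {
    st <- c(-1, -3, 1, 3, 3)
    names(st) <- c("glycerol_c", "atp_c", tag_id, "adp_c", "pi_c")
    for (ch in chains) {
      fid <- fa_reg$id[fa_reg$label == ch]
      st[paste0(fid, "_c")] <- -3 / length(chains)
    }
    add_rxn(paste0("TAGSYN_", sub("_c$", "", tag_id)),
            sprintf("TAG assembly %s (lumped)", label), st,
            subsystem = "lipid synthesis")
  }
  if (length(chains_a) > 0) add_tag("tag_a_c", chains_a, "(12:0/14:0/16:0)")
  if (length(chains_b) > 0) add_tag("tag_b_c", chains_b, "(16:1/18:1/18:2)")

  # Amino-acid catabolism: oxidative deamination to acetyl-CoA units.
  for (i in seq_len(nrow(aa_reg))) {
    f <- parse_formula(aa_reg$formula[i])
    n_c <- f[["C"]]
    n_ac <- floor(n_c / 2)
    st <- c(-1, -n_ac, n_ac)
    names(st) <- c(paste0(aa_reg$abbrev[i], "_c"), "coa_c", "accoa_c")
    if (n_c - 2 * n_ac > 0) st["co2_c"] <- n_c - 2 * n_ac
    if ("N" %in% names(f)) st["nh3_c"] <- f[["N"]]
    if ("S" %in% names(f)) {
      st["so4_c"] <- f[["S"]]
      st["o2_c"] <- -2 * f[["S"]]  # sulfur leaves oxidized
    }
    add_rxn(paste0("CAT_", aa_reg$abbrev[i]),
            paste(aa_reg$name[i], "catabolism (lumped)"),
            st, subsystem = "amino acid catabolism")
  }

  # Biomass assembly and drains.
  bio <- assemble_biomass_reaction(spec)
  missing_pool <- setdiff(names(bio$stoichiometry), mets$id)
  if (length(missing_pool) > 0) {
    stop(sprintf("infeasible parameters: biomass precursor(s) without source: %s",
                 paste(missing_pool, collapse = ", ")))
  }
  add_rxn(bio$id, bio$name, bio$stoichiometry, lb = bio$lower_bound,
          ub = bio$upper_bound, subsystem = "biomass", balance = FALSE)
  add_rxn("DM_biomass", "biomass drain", c(biomass_c = -1),
          subsystem = "demand", balance = FALSE)
  for (i in seq_len(nrow(fa_reg))) {
    add_rxn(paste0("DM_", fa_reg$id[i]),
            sprintf("%s drain (%s)", fa_reg$name[i], fa_reg$label[i]),
            stats::setNames(-1, paste0(fa_reg$id[i], "_c")),
            subsystem = "demand", balance = FALSE)
  }

  # Decoy dead ends: balanced isomerase stubs to nowhere, as real
  # reconstructions carry. Seed-dependent count ordering only.
  rng <- local_rng(params$seed)
  if (params$n_decoys > 0) {
    for (k in seq_len(params$n_decoys)) {
      did <- sprintf("decoy%d_c", k)
      add_met(did, sprintf("orphan isomer %d", k), "c", SYNTH_SPECIES[["accoa"]])
      formulas[did] <- SYNTH_SPECIES[["accoa"]]
      add_rxn(sprintf("DECOY_%d", k), sprintf("orphan isomerase %d", k),
              stats::setNames(c(-1, 1), c("accoa_c", did)),
              lb = 0, subsystem = "decoy", balance = FALSE)
    }
  }

  # Cosmetic shuffle: metabolite and reaction order carry no meaning.
  met_order <- rng$sample(nrow(mets))
  rxn_order <- rng$sample(nrow(rxns))
  mets <- mets[met_order, ]
  rxns <- rxns[rxn_order, ]
  stoich <- stoich[rxns$id]

  model <- metabolic_model(
    id = sprintf("synthetic_larva_seed%d", params$seed),
    metabolites = mets, reactions = rxns, stoichiometry = stoich,
    compartments = c(e = "extracellular", c = "cytosol", m = "mitochondrion"),
    objective = list(reaction = "BIOMASS", direction = "maximize"),
    genes = sprintf("g%04d", seq_len(nrow(rxns))))
  model <- apply_diet(model, reference_diet(params))
  attr(model, "biomass_spec") <- spec
  attr(model, "params") <- params
  model
}

# Small self-contained RNG wrapper: isolates the generator's cosmetic
# shuffling from the session RNG state.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv())
  env$sample <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- sample.int(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
    out
  }
  env
}
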