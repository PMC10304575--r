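# Shared fixtures: tiny hand-built models and a random-network generator
# used by the property tests. Everything is built in code at test time.

# Linear chain: EX_A (uptake <= 10) -> A --T--> B --BIO--> (drain).
# FBA optimum is 10 by inspection.
chain_model <- function(uptake = 10) {
  metabolic_model(
    id = "chain",
    metabolites = data.frame(
      id = c("A", "B"), name = c("A", "B"), compartment = "c",
      formula = c("C2H4O2", "C2H4O2"), charge = NA_integer_,
      stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_A", "T", "BIO"),
      name = c("A exchange", "conversion", "biomass"),
      lower_bound = c(-uptake, 0, 0), upper_bound = c(1000, 1000, 1000),
      gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_A = c(A = -1), T = c(A = -1, B = 1), BIO = c(B = -1)),
    compartments = c(c = "cytosol"),
    objective = list(reaction = "BIO", direction = "maximize"))
}

# Branched toy: one substrate feeds two competing products with different
# stoichiometric yields; used against the vertex oracle.
branched_model <- function() {
  metabolic_model(
    id = "branched",
    metabolites = data.frame(
      id = c("S", "P", "Q"), name = c("S", "P", "Q"), compartment = "c",
      formula = NA_character_, charge = NA_integer_, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_S", "MK_P", "MK_Q", "DM_P", "DM_Q"),
      name = c("S uptake", "P synthesis", "Q synthesis", "P drain", "Q drain"),
      lower_bound = c(-6, 0, 0, 0, 0), upper_bound = c(1000, 4, 1000, 1000, 1000),
      gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_S = c(S = -1),
                         MK_P = c(S = -1, P = 1),
                         MK_Q = c(S = -2, Q = 1),
                         DM_P = c(P = -1), DM_Q = c(Q = -1)),
    compartments = c(c = "cytosol"),
    objective = list(reaction = "DM_P", direction = "maximize"))
}

# Random small metabolic network with an uptake -> conversions -> drain
# shape; always feasible (zero flux) and bounded. n_rxn counts total
# reactions (>= 3).
random_network <- function(n_rxn = 6, seed = 1) {
  set.seed(seed)
  n_int <- max(1L, n_rxn - 2L)            # internal conversions
  n_met <- sample(2:4, 1)
  mets <- paste0("m", seq_len(n_met))
  rxn_ids <- c("EX_in", paste0("R", seq_len(n_int)), "DM_out")
  st <- list(EX_in = stats::setNames(-1, mets[1]))
  for (k in seq_len(n_int)) {
    from <- sample(mets, 1)
    to <- sample(setdiff(mets, from), 1)
    st[[paste0("R", k)]] <- stats::setNames(
      c(-sample(1:2, 1), sample(1:2, 1)), c(from, to))
  }
  st[["DM_out"]] <- stats::setNames(-1, mets[n_met])
  lb <- c(-round(runif(1, 1, 10), 1), rep(0, n_int), 0)
  rev <- which(stats::runif(n_int) < 0.3)
  lb[1 + rev] <- -1000
  metabolic_model(
    id = sprintf("rand%d", seed),
    metabolites = data.frame(id = mets, name = mets, compartment = "c",
                             formula = NA_character_, charge = NA_integer_,
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = rxn_ids, name = rxn_ids,
                           lower_bound = lb, upper_bound = 1000,
                           gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = st,
    compartments = c(c = "cytosol"),
    objective = list(reaction = "DM_out", direction = "maximize"))
}

# The default synthetic larva network is expensive enough to build that the
# suite shares one instance (and its reference diet).
.fixture_env <- new.env()
synth_default <- function() {
  if (is.null(.fixture_env$model)) {
    .fixture_env$model <- generate_network()
    .fixture_env$diet <- reference_diet()
  }
  .fixture_env$model
}
synth_diet <- function() {
  synth_default()
  .fixture_env$diet
}

# A deliberately small larva network for the expensive whole-model scans.
synth_small <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_network(synthetic_network_params(
      n_amino_acids = 3, fatty_acid_set = c("C12:0", "C18:1"), n_decoys = 1,
      seed = 11))
  }
  .fixture_env$small
}
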