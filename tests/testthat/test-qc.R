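test_that("exchange detection flags exactly the single-metabolite reactions", {
  m <- chain_model()
  expect_identical(find_exchange_reactions(m), c("EX_A", "BIO"))
  m2 <- branched_model()
  expect_setequal(find_exchange_reactions(m2), c("EX_S", "DM_P", "DM_Q"))
})

test_that("dead-end detection respects reaction reversibility", {
  # D is only produced (irreversible producer, no consumer)
  m <- metabolic_model(
    id = "deadend",
    metabolites = data.frame(id = c("A", "B", "D"), name = c("A", "B", "D"),
                             compartment = "c", formula = NA_character_,
                             charge = NA_integer_, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_A", "R1", "R2", "DM_B"),
      name = c("uptake", "split", "rev", "drain"),
      lower_bound = c(-10, 0, -1000, 0), upper_bound = 1000,
      gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_A = c(A = -1),
                         R1 = c(A = -1, B = 1, D = 1),
                         R2 = c(A = -1, B = 1),
                         DM_B = c(B = -1)),
    compartments = c(c = "cytosol"),
    objective = list(reaction = "DM_B", direction = "maximize"))
  expect_identical(detect_dead_ends(m), "D")

  # making the producer reversible clears the dead end
  m2 <- set_bounds(m, "R1", lower = -1000)
  expect_length(detect_dead_ends(m2), 0)
})

test_that("blocked reactions are those with zero flux in every solution", {
  m <- metabolic_model(
    id = "blocked",
    metabolites = data.frame(id = c("A", "B", "D", "E"),
                             name = c("A", "B", "D", "E"),
                             compartment = "c", formula = NA_character_,
                             charge = NA_integer_, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("EX_A", "R1", "DM_B", "R_dead", "R_chain"),
      name = "r", lower_bound = c(-10, 0, 0, 0, 0), upper_bound = 1000,
      gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_A = c(A = -1),
                         R1 = c(A = -1, B = 1),
                         DM_B = c(B = -1),
                         R_dead = c(A = -1, D = 1),   # D has no consumer
                         R_chain = c(D = -1, E = 1)), # downstream of dead end
    compartments = c(c = "cytosol"),
    objective = list(reaction = "DM_B", direction = "maximize"))
  blocked <- find_blocked_reactions(m)
  expect_setequal(blocked, c("R_dead", "R_chain"))

  # the open producing-consuming chain is never blocked
  expect_length(find_blocked_reactions(chain_model()), 0)
})

test_that("reactions touching dead-end metabolites are blocked (subset law)", {
  for (seed in c(2, 5, 8, 13)) {
    m <- random_network(7, seed)
    dead <- detect_dead_ends(m)
    if (length(dead) == 0) next
    blocked <- find_blocked_reactions(m)
    touching <- m$reactions$id[vapply(m$reactions$id, function(rid) {
      any(names(m$stoichiometry[[rid]]) %in% dead)
    }, logical(1))]
    expect_true(all(touching %in% blocked))
  }
})

test_that("elemental balance classifies balanced, unbalanced and unparseable", {
  m <- metabolic_model(
    id = "bal",
    metabolites = data.frame(
      id = c("glc", "lac", "x"),
      name = c("glucose", "lactate", "mystery"),
      compartment = "c",
      formula = c("C6H12O6", "C3H6O3", NA),
      charge = NA_integer_, stringsAsFactors = FALSE),
    reactions = data.frame(
      id = c("FERM", "EX_glc", "MYST"),
      name = "r", lower_bound = 0, upper_bound = 1000,
      gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(FERM = c(glc = -1, lac = 2),
                         EX_glc = c(glc = -1),
                         MYST = c(glc = -1, x = 1)),
    compartments = c(c = "cytosol"),
    objective = list(reaction = "FERM", direction = "maximize"))
  bal <- check_mass_balance(m)
  expect_true(bal$balanced[bal$reaction == "FERM"])
  expect_false(bal$balanced[bal$reaction == "EX_glc"])
  expect_match(bal$imbalance[bal$reaction == "EX_glc"], "C: -6")
  expect_true(bal$unparseable[bal$reaction == "MYST"])
  expect_false(bal$balanced[bal$reaction == "MYST"])
})

test_that("the QC report aggregates counts into 2-decimal percentages", {
  m <- synth_small()
  qc <- qc_report(m)
  expect_equal(qc$n_metabolites, nrow(m$metabolites))
  expect_equal(qc$pct_dead_end_metabolites,
               round(100 * length(qc$dead_end_metabolites) / qc$n_metabolites, 2))
  expect_equal(qc$pct_blocked_reactions,
               round(100 * length(qc$blocked_reactions) / qc$n_reactions, 2))
  expect_equal(qc$pct_exchange_reactions,
               round(100 * length(qc$exchange_reactions) / qc$n_reactions, 2))
  for (p in c(qc$pct_dead_end_metabolites, qc$pct_blocked_reactions,
              qc$pct_unbalanced_reactions, qc$pct_exchange_reactions)) {
    expect_gte(p, 0); expect_lte(p, 100)
  }
  # the seeded decoy is a dead end and blocked
  expect_true("decoy1_c" %in% qc$dead_end_metabolites)
  expect_true("DECOY_1" %in% qc$blocked_reactions)
})

test_that("QC percentages are invariant under reordering", {
  m <- synth_small()
  perm_m <- order(m$metabolites$id)
  perm_r <- order(m$reactions$id)
  m2 <- m
  m2$metabolites <- m$metabolites[perm_m, ]
  m2$reactions <- m$reactions[perm_r, ]
  m2$stoichiometry <- m$stoichiometry[m2$reactions$id]
  a <- qc_report(m)
  b <- qc_report(m2)
  expect_equal(a$pct_dead_end_metabolites, b$pct_dead_end_metabolites)
  expect_equal(a$pct_blocked_reactions, b$pct_blocked_reactions)
  expect_equal(a$pct_unbalanced_reactions, b$pct_unbalanced_reactions)
  expect_equal(a$pct_exchange_reactions, b$pct_exchange_reactions)
})
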