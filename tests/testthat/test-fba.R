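test_that("FBA solves the linear chain and the branched toy exactly", {
  sol <- fba(chain_model(uptake = 10))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes["EX_A"]), -10)
  expect_lt(sol$residual, 1e-9)

  # branched network cross-checked against the vertex oracle
  m <- branched_model()
  want <- oracle_fba(m)
  got <- fba(m)
  expect_equal(got$objective_value, want$objective, tolerance = 1e-7)
})

test_that("FBA status is faithful for infeasible bound sets", {
  m <- chain_model()
  # force positive biomass flux with all uptake closed
  m <- set_bounds(m, "EX_A", lower = 0)
  m <- set_bounds(m, "BIO", lower = 5)
  sol <- fba(m)
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("FBA matches the vertex oracle over random small networks", {
  for (seed in 1:25) {
    m <- random_network(sample(4:8, 1), seed)
    got <- fba(m)
    want <- oracle_fba(m)
    expect_identical(got$status, want$status)
    if (got$status == "optimal") {
      expect_equal(got$objective_value, want$objective, tolerance = 1e-7)
      expect_lt(got$residual, 1e-6 * max(1, max(abs(got$fluxes))))
    }
  }
})

test_that("FVA honors fixed reactions and full-optimum constraints", {
  m <- chain_model()
  m <- set_bounds(m, "T", lower = 3, upper = 3)
  r <- fva(m, fraction = 0.9, reactions = "T")$ranges
  expect_equal(r$min_flux, 3)
  expect_equal(r$max_flux, 3)

  # at fraction 1 the objective reaction is pinned to its unique optimum
  m2 <- chain_model()
  r2 <- fva(m2, fraction = 1, reactions = "BIO")$ranges
  expect_equal(r2$min_flux, 10, tolerance = 1e-7)
  expect_equal(r2$max_flux, 10, tolerance = 1e-7)
})

test_that("FVA extrema agree with the oracle and sandwich the FBA flux", {
  for (seed in c(3, 9, 14)) {
    m <- random_network(8, seed)
    sol <- fba(m)
    if (sol$status != "optimal") next
    res <- fva(m, fraction = 0.9)
    for (i in seq_len(nrow(res$ranges))) {
      rid <- res$ranges$reaction[i]
      want <- oracle_fva_range(m, rid, 0.9)
      expect_equal(res$ranges$min_flux[i], unname(want["min"]), tolerance = 1e-7)
      expect_equal(res$ranges$max_flux[i], unname(want["max"]), tolerance = 1e-7)
    }
    # FVA sandwich: the optimum's flux vector lies within every range
    res1 <- fva(m, fraction = 1 - 1e-9)
    for (i in seq_len(nrow(res1$ranges))) {
      v <- sol$fluxes[[res1$ranges$reaction[i]]]
      expect_gte(v, res1$ranges$min_flux[i] - 1e-6)
      expect_lte(v, res1$ranges$max_flux[i] + 1e-6)
    }
  }
})

test_that("FVA validates its fraction and base problem", {
  expect_error(fva(chain_model(), fraction = 0), "fraction")
  expect_error(fva(chain_model(), fraction = 1.2), "fraction")
  m <- chain_model()
  m <- set_bounds(m, "EX_A", lower = 0)
  m <- set_bounds(m, "BIO", lower = 5)
  expect_error(fva(m, 0.9), "infeasible")
})

test_that("growth-change arithmetic matches the reporting convention", {
  expect_equal(growth_change_percent(5, 5), 0)
  expect_equal(growth_change_percent(1, 1.32), 32, tolerance = 1e-9)
  expect_equal(round(growth_change_percent(0.029, 0.051), 2), 75.86)
  expect_error(growth_change_percent(0, 1), "zero")
  s1 <- fba(chain_model(10))
  s2 <- fba(chain_model(15))
  expect_equal(growth_change_percent(s1, s2), 50, tolerance = 1e-7)
})

test_that("uptake relaxation never decreases the optimum", {
  # the LP-relaxation mechanism behind "doubled glucose, no growth increase"
  for (seed in 1:20) {
    m <- random_network(6, seed)
    base <- fba(m)$objective_value
    k <- match("EX_in", m$reactions$id)
    m2 <- m
    m2$reactions$lower_bound[k] <- 2 * m$reactions$lower_bound[k]
    expect_gte(fba(m2)$objective_value, base - 1e-9)
  }
})

test_that("perturbation experiments scale the right exchanges", {
  m <- synth_default()
  d <- synth_diet()
  res <- run_perturbation_experiment(m, d, "doubled_single_AA",
                                     single_aa = "Lysine")
  expect_identical(res$targets, "EX_lys_e")
  expect_gte(res$growth_change_percent, -1e-9)

  res2 <- run_perturbation_experiment(m, d, "doubled_EAA")
  expect_setequal(res2$targets,
                  unname(vapply(essential_amino_acids(), exchange_id,
                                character(1))))

  expect_error(run_perturbation_experiment(m, d, "doubled_single_AA"),
               "single_aa")
  expect_error(
    run_perturbation_experiment(m, d, "doubled_glucose",
                                targets = "EX_missing_e"),
    "not present")
})
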