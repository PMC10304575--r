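test_that("carbon conversion efficiency matches the two orientations", {
  # all glucose carbon routed into laurate: 6 C in, 6 C out
  inp <- carbon_efficiency_input(c(EX_glc_e = 1), c(EX_glc_e = 6),
                                 drain_rate = 0.5, drain_carbon = 12)
  expect_equal(compute_cce(inp, "printed"), 100)
  expect_equal(compute_cce(inp, "efficiency"), 100)

  half <- carbon_efficiency_input(c(EX_glc_e = 1), c(EX_glc_e = 6),
                                  drain_rate = 0.25, drain_carbon = 12)
  expect_equal(compute_cce(half, "efficiency"), 50)
  expect_equal(compute_cce(half, "printed"), 200)
})

test_that("orientation duality and the doubling law hold for random inputs", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(1:5, 1)
    inp <- carbon_efficiency_input(
      stats::setNames(stats::runif(n, 0.01, 2), paste0("EX_", seq_len(n))),
      stats::setNames(sample(1:27, n, replace = TRUE), paste0("EX_", seq_len(n))),
      drain_rate = stats::runif(1, 0.01, 1),
      drain_carbon = sample(12:18, 1))
    p <- compute_cce(inp, "printed")
    e <- compute_cce(inp, "efficiency")
    expect_equal(p * e, 10000, tolerance = 1e-6)

    doubled <- inp
    doubled$uptake_rates <- inp$uptake_rates * 2
    expect_equal(compute_cce(doubled, "printed"), 2 * p, tolerance = 1e-9)
    expect_equal(compute_cce(doubled, "efficiency"), e / 2, tolerance = 1e-9)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(carbon_efficiency_input(c(a = -1), c(a = 6), 1, 12), ">= 0")
  expect_error(carbon_efficiency_input(c(a = 1), c(b = 6), 1, 12), "share names")
  zero_in <- carbon_efficiency_input(c(a = 0), c(a = 6), 1, 12)
  expect_error(compute_cce(zero_in, "efficiency"), "zero dietary carbon")
  zero_out <- carbon_efficiency_input(c(a = 1), c(a = 6), 0, 12)
  expect_error(compute_cce(zero_out, "printed"), "zero drain")
})

test_that("a loss-free linear pathway converts carbon at 100%", {
  # EX_G -(uptake u)-> G -> 2 L (C6 -> 2 x C3), drain L
  m <- metabolic_model(
    id = "lossfree",
    metabolites = data.frame(id = c("G", "L"), name = c("G", "L"),
                             compartment = "c",
                             formula = c("C6H12O6", "C3H6O3"),
                             charge = NA_integer_, stringsAsFactors = FALSE),
    reactions = data.frame(id = c("EX_G", "SPLIT", "DM_L"), name = "r",
                           lower_bound = c(-2, 0, 0), upper_bound = 1000,
                           gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_G = c(G = -1), SPLIT = c(G = -1, L = 2),
                         DM_L = c(L = -1)),
    compartments = c(c = "cytosol"),
    objective = list(reaction = "DM_L", direction = "maximize"))
  tab <- cce_experiment(m, exchange_bounds(c(EX_G = 2)), "DM_L", fraction = 1)
  expect_equal(tab$cce_efficiency, 100, tolerance = 1e-6)
  expect_equal(tab$cce_printed, 100, tolerance = 1e-6)

  # zero-uptake diet: no dietary carbon, the statistic is undefined
  expect_error(cce_experiment(m, exchange_bounds(c(EX_G = 0)), "DM_L"),
               "zero dietary carbon")
})

test_that("the diet comparison obeys the carbon-intake rescaling law", {
  m <- synth_default()
  d <- synth_diet()
  drains <- grep("^DM_c\\d+$", m$reactions$id, value = TRUE)
  ref <- cce_experiment(m, d, drains, diet_label = "reference")
  dbl <- cce_experiment(m, scale_uptake(d, "EX_glc_e", 2), drains,
                        diet_label = "doubled_glucose")
  merged <- merge(ref, dbl, by = "drain", suffixes = c("_ref", "_dbl"))

  # total dietary carbon of each diet, computed independently from the
  # bounds and formulas
  carbon_in <- function(bounds) {
    sum(vapply(names(bounds), function(id) {
      met <- names(m$stoichiometry[[id]])
      f <- m$metabolites$formula[m$metabolites$id == met]
      carbon_count(f) * bounds[[id]]
    }, numeric(1)))
  }
  cin_ref <- carbon_in(d)
  cin_dbl <- carbon_in(scale_uptake(d, "EX_glc_e", 2))
  expect_equal(cin_dbl - cin_ref, 6 * d[["EX_glc_e"]], tolerance = 1e-9)

  # efficiency changes decompose exactly into drain gain over carbon gain:
  # a drain rising slower than total carbon intake loses efficiency, one
  # rising faster gains it
  expect_equal(merged$cce_efficiency_dbl / merged$cce_efficiency_ref,
               (merged$drain_rate_dbl / merged$drain_rate_ref) /
                 (cin_dbl / cin_ref),
               tolerance = 1e-6)

  # duality holds on computed experiment rows too
  ok <- !is.na(ref$cce_printed)
  expect_equal(ref$cce_printed[ok] * ref$cce_efficiency[ok],
               rep(10000, sum(ok)), tolerance = 1e-6)
})
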