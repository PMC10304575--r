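test_that("composition normalization is proportional, exclusive and idempotent", {
  out <- normalize_composition(c(A = 50, B = 30, water = 20), "water")
  expect_equal(out, c(A = 0.625, B = 0.375))
  expect_equal(normalize_composition(c(A = 100)), c(A = 1))
  expect_error(normalize_composition(c(A = 0, B = 0)), "normalize")
  expect_error(normalize_composition(c(water = 5), "water"), "normalize")

  x <- c(a = 3, b = 7, c = 10)
  once <- normalize_composition(x)
  expect_equal(normalize_composition(once), once)
  expect_equal(sum(once), 1)

  # the measured profile restricted to the six modeled fatty acids
  fa <- larva_fatty_acid_profile()
  starred <- stats::setNames(fa$g_per_100g_fat, fa$label)[fa$modeled]
  frac <- normalize_composition(starred)
  expect_equal(sum(frac), 1)
  expect_equal(unname(frac["C12:0"]), 29.4 / 92.14, tolerance = 1e-12)
})

test_that("TAG composition selection covers declared and measured splits", {
  fa <- larva_fatty_acid_profile()
  prof <- stats::setNames(fa$g_per_100g_fat, fa$label)
  sel <- select_tag_composition(prof)
  expect_equal(unname(sel$tag_split), c(0.49, 0.51))
  expect_identical(sel$tag_a_chains, c("C12:0", "C14:0", "C16:0"))
  expect_identical(sel$tag_b_chains, c("C16:1", "C18:1", "C18:2"))

  # recomputed from the printed masses: A = 45.6, B = 46.54
  meas <- select_tag_composition(prof, split = "measured")
  expect_equal(unname(meas$tag_split["A"]), 45.6 / 92.14, tolerance = 1e-9)
  expect_equal(unname(meas$tag_split["B"]), 46.54 / 92.14, tolerance = 1e-9)
  expect_equal(round(unname(meas$tag_split), 3), c(0.495, 0.505))

  only_a <- prof
  only_a[c("C16:1", "C18:1", "C18:2")] <- 0
  sel_a <- select_tag_composition(only_a, split = "measured")
  expect_equal(unname(sel_a$tag_split), c(1, 0))

  expect_error(select_tag_composition(prof[c("C12:0", "C14:0")]),
               "lacks TAG constituent")
})

test_that("cholesterol grafting preserves unit total for any donor ratio", {
  base <- c(A = 0.5, B = 0.5)
  expect_equal(approximate_cholesterol(base, 0), base)
  out <- approximate_cholesterol(base, 0.02)
  expect_equal(out, c(A = 0.49, B = 0.49, cholesterol = 0.02))
  for (r in seq(0, 0.2, by = 0.025)) {
    expect_equal(sum(approximate_cholesterol(base, r)), 1, tolerance = 1e-12)
  }
  expect_error(approximate_cholesterol(base, 0.3), "0, 0.2")
  expect_error(approximate_cholesterol(c(A = 0.4, B = 0.4), 0.1), "sum to 1")
})

test_that("biomass coefficients are mass fractions over molar masses", {
  # single metabolite, fraction 1, DW 1 g, molar mass 1 g/mmol -> 1 mmol
  spec1 <- structure(list(coefficients = c(x_c = 1 * 1 / 1),
                          molar_masses = c(x_c = 1),
                          larva_dry_weight = 1), class = "biomass_spec")
  rxn <- assemble_biomass_reaction(spec1)
  expect_equal(unname(rxn$stoichiometry["x_c"]), -1)
  expect_equal(unname(rxn$stoichiometry["biomass_c"]), 1)

  # glucose at half the mass of a 0.18 g larva
  expect_equal(0.5 * 0.18 / 0.18015, 0.4996, tolerance = 1e-4)

  expect_error(
    assemble_biomass_reaction(spec1, molar_masses = c(other = 1)),
    "no molar mass")
})

test_that("the assembled biomass consumes exactly one larva dry weight", {
  spec <- build_biomass_spec(default_larva_assay())
  recon <- sum(spec$coefficients * spec$molar_masses[names(spec$coefficients)])
  expect_equal(recon, spec$larva_dry_weight, tolerance = 1e-9)
  expect_true(all(spec$coefficients >= 0))
  expect_equal(sum(spec$normalized_mass_fractions), 1, tolerance = 1e-9)
  # the validated composition ratios: 70% amino acids, 16% fat
  expect_equal(unname(spec$normalized_mass_fractions["amino_acids"]), 0.70,
               tolerance = 1e-9)
  expect_equal(unname(spec$normalized_mass_fractions["fat"]), 0.16,
               tolerance = 1e-9)
})

test_that("fatty-acid bookkeeping reproduces the saturation structure", {
  bk <- fatty_acid_bookkeeping()
  expect_equal(bk$saturated_g, 29.4 + 5.75 + 10.45 + 3.5)
  expect_equal(bk$saturated_pct, 49)
  expect_equal(bk$modeled_coverage_g, 92.14)
  expect_equal(bk$lauric_pct, 29)
  expect_equal(bk$oleic_pct, 21)
  expect_equal(bk$polyunsaturated_pct, 20)
  # the profile's monounsaturated entries sum to 27.47 g/100 g; the rounded
  # share from the printed table is therefore 27 (reported narratives that
  # round the same set to 28 are not reproducible from the table itself)
  expect_equal(bk$monounsaturated_g, 27.47)
  expect_equal(bk$monounsaturated_pct, 27)
})

test_that("round-half-away rounding matches the reporting style", {
  expect_equal(round_half_away(19.8), 20)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.5), 3)  # banker's rounding would give 2
  expect_equal(round_half_away(0.0125, 3), 0.013)
})
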