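test_that("consumed mass is applied minus residue with validation", {
  tab <- diet_ingredient_table()
  expect_equal(consumed_mass(tab[1, c("total_g", "residue_g")]), 846)   # glucose
  expect_equal(consumed_mass(tab[2, c("total_g", "residue_g")]), 560)   # protein
  expect_equal(consumed_mass(100, 100), 0)
  expect_error(consumed_mass(10, 11), "exceeds")
  expect_error(consumed_mass(-1, 0), ">= 0")
})

test_that("the g -> mg/larva/day -> mmol/larva/day chain reproduces every printed rate", {
  tab <- diet_amino_acid_table()
  # feed the printed mg/larva/day column through the conversion with unit
  # larva-days; every printed mmol value must come back to 3 decimals
  bounds <- aa_rates(
    consumed_aa_mass = stats::setNames(tab$mg_per_larva_day / 1000, tab$amino_acid),
    larva_count = 1, duration_days = 1)
  detail <- attr(bounds, "detail")
  expect_equal(detail$mg_per_larva_day, tab$mg_per_larva_day, tolerance = 1e-12)
  expect_equal(round(detail$mmol_per_larva_day, 3), tab$mmol_per_larva_day)
  # spot values: lysine and glycine
  expect_equal(round(bounds[["EX_lys_e"]], 3), 0.012)
  expect_equal(round(bounds[["EX_gly_e"]], 3), 0.013)
})

test_that("amino-acid rates can be apportioned from the dietary profile", {
  tab <- diet_amino_acid_table()
  prof <- stats::setNames(tab$mg_per_100g_protein, tab$amino_acid)
  bounds <- aa_rates(profile = prof, consumed_protein_g = 560,
                     larva_count = 5357, duration_days = 9)
  expect_true(all(bounds > 0))
  # proportionality: rates scale with the profile
  detail <- attr(bounds, "detail")
  expect_equal(detail$consumed_g, 560 * prof / sum(prof), ignore_attr = TRUE)

  expect_equal(
    as.numeric(aa_rates(consumed_aa_mass = c(Lysine = 0, Glycine = 0),
                        larva_count = 10, duration_days = 9)),
    c(0, 0))
  expect_error(aa_rates(consumed_aa_mass = c(Lysine = 1),
                        larva_count = 0, duration_days = 9), ">= 1")
  expect_error(aa_rates(consumed_aa_mass = c(Unobtainium = 1),
                        larva_count = 1, duration_days = 1),
               "no molar mass|unknown")
})

test_that("applying a diet closes unlisted uptakes and is idempotent", {
  m <- synth_small()
  d <- reference_diet(attr(m, "params"))

  once <- apply_diet(m, d)
  twice <- apply_diet(once, d)
  expect_identical(once$reactions, twice$reactions)

  expect_equal(once$reactions$lower_bound[once$reactions$id == "EX_lys_e"],
               -unname(d[["EX_lys_e"]]))

  # empty diet: every non-whitelisted uptake closed, growth impossible
  starved <- apply_diet(m, exchange_bounds(stats::setNames(numeric(0), character(0))))
  expect_equal(fba(starved)$objective_value, 0, tolerance = 1e-9)
  # whitelisted species stay open
  expect_lt(starved$reactions$lower_bound[starved$reactions$id == "EX_o2_e"], 0)

  expect_error(apply_diet(m, exchange_bounds(c(EX_nope_e = 1))),
               "non-exchange or missing")
})

test_that("uptake scaling multiplies targets only and inverts exactly", {
  b <- exchange_bounds(c(EX_glc_e = 0.05, EX_lys_e = 0.012))
  expect_equal(as.numeric(scale_uptake(b, names(b), 1)), as.numeric(b))
  s <- scale_uptake(b, "EX_glc_e", 2)
  expect_equal(s[["EX_glc_e"]], 0.10)
  expect_equal(s[["EX_lys_e"]], 0.012)
  back <- scale_uptake(s, "EX_glc_e", 0.5)
  expect_equal(as.numeric(back), as.numeric(b))
  expect_error(scale_uptake(b, "EX_xyz_e", 2), "unknown")
  expect_error(scale_uptake(b, "EX_glc_e", 0), "> 0")

  # doubling the essential set on the reference diet
  d <- reference_diet()
  eaa_ids <- vapply(essential_amino_acids(), exchange_id, character(1))
  dd <- scale_uptake(d, eaa_ids, 2)
  expect_equal(dd[["EX_val_e"]], 0.034)
  expect_equal(dd[["EX_lys_e"]], 0.024)
  expect_equal(dd[["EX_gly_e"]], d[["EX_gly_e"]])  # non-essential untouched
})
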