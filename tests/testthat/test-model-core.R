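test_that("model construction enforces the structural invariants", {
  m <- chain_model()
  expect_s3_class(m, "metabolic_model")
  expect_true(validate_model(m))

  dup <- m
  dup$metabolites$id[2] <- "A"
  expect_error(validate_model(dup), "duplicate metabolite")

  badcomp <- m
  badcomp$metabolites$compartment[1] <- "x"
  expect_error(validate_model(badcomp), "not declared")

  badbound <- m
  badbound$reactions$lower_bound[1] <- 2000
  expect_error(validate_model(badbound), "lower_bound > upper_bound")

  badstoich <- m
  badstoich$stoichiometry$T <- c(A = -1, Z = 1)
  expect_error(validate_model(badstoich), "unknown metabolite")

  noobj <- m
  noobj$objective$reaction <- ""
  expect_error(validate_model(noobj), "objective is empty")

  ghostobj <- m
  ghostobj$objective$reaction <- "NOPE"
  expect_error(validate_model(ghostobj), "does not exist")
})

test_that("stoichiometric matrix reproduces the per-reaction coefficients", {
  m <- chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2, 3))
  expect_equal(S["A", "EX_A"], -1)
  expect_equal(S["A", "T"], -1)
  expect_equal(S["B", "T"], 1)
  expect_equal(S["B", "BIO"], -1)
  expect_equal(S["B", "EX_A"], 0)

  # a 2 A -> B column
  m2 <- branched_model()
  S2 <- stoichiometric_matrix(m2)
  expect_equal(S2["S", "MK_Q"], -2)
  expect_equal(S2["Q", "MK_Q"], 1)

  # random models: column sums match an independent per-reaction summation,
  # and the nonzero pattern matches the stoichiometry maps exactly
  for (seed in 1:5) {
    r <- random_network(6, seed)
    S <- stoichiometric_matrix(r)
    for (rid in r$reactions$id) {
      st <- r$stoichiometry[[rid]]
      expect_equal(sum(S[, rid]), sum(st))
      expect_equal(sum(S[, rid] != 0), length(st))
      expect_equal(S[names(st), rid], unname(st), ignore_attr = TRUE)
    }
  }
})

test_that("models round-trip exactly through every supported format", {
  models <- list(branched_model(), synth_small())
  same_model <- function(a, b) {
    expect_identical(a$metabolites$id, b$metabolites$id)
    expect_identical(a$metabolites$formula, b$metabolites$formula)
    expect_identical(a$reactions$id, b$reactions$id)
    expect_identical(a$reactions$lower_bound, b$reactions$lower_bound)
    expect_identical(a$reactions$upper_bound, b$reactions$upper_bound)
    expect_identical(a$reactions$gpr, b$reactions$gpr)
    expect_identical(a$objective, b$objective)
    expect_identical(a$genes, b$genes)
    for (rid in a$reactions$id) {
      sa <- a$stoichiometry[[rid]]
      sb <- b$stoichiometry[[rid]]
      expect_identical(sort(names(sa)), sort(names(sb)))
      expect_identical(unname(sa[sort(names(sa))]), unname(sb[sort(names(sa))]))
    }
  }
  for (m in models) {
    p <- tempfile(fileext = ".json")
    write_model(m, p, "json")
    same_model(m, read_model(p))
    p <- tempfile(fileext = ".xml")
    write_model(m, p, "sbml")
    same_model(m, read_model(p, "sbml"))
    p <- tempfile()
    write_model(m, p, "tabular")
    same_model(m, read_model(p, "tabular"))
  }
})

test_that("GPR strings and subsystems survive a round trip unevaluated", {
  m <- chain_model()
  m$reactions$gpr <- c("", "(g1 and g2) or g3", "g4")
  m$reactions$subsystem <- c("exchange", "core", "biomass")
  m$genes <- c("g1", "g2", "g3", "g4")
  for (fmt in c("json", "sbml", "tabular")) {
    p <- tempfile(fileext = switch(fmt, json = ".json", sbml = ".xml", ""))
    write_model(m, p, fmt)
    b <- read_model(p, fmt)
    expect_identical(b$reactions$gpr, m$reactions$gpr)
    expect_identical(b$reactions$subsystem, m$reactions$subsystem)
    expect_identical(b$genes, m$genes)
  }
})

test_that("readers report malformed input and writers refuse invalid models", {
  expect_error(read_model(tempfile(), "json"), "does not exist")
  bad <- tempfile(fileext = ".json")
  writeLines('{"metabolites": []}', bad)
  expect_error(read_model(bad, "json"), "lacks|no ")
  badx <- tempfile(fileext = ".xml")
  writeLines("<not-sbml/>", badx)
  expect_error(read_model(badx, "sbml"), "model")

  m <- chain_model()
  m$objective$reaction <- "NOPE"
  expect_error(write_model(m, tempfile(fileext = ".json"), "json"),
               "does not exist")
})

test_that("minimal single-reaction SBML documents are readable", {
  p <- tempfile(fileext = ".xml")
  m <- metabolic_model(
    id = "mini",
    metabolites = data.frame(id = "A", name = "A", compartment = "c",
                             formula = NA_character_, charge = NA_integer_,
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = "EX_A", name = "A exchange",
                           lower_bound = -10, upper_bound = 10,
                           gpr = "", subsystem = "", stringsAsFactors = FALSE),
    stoichiometry = list(EX_A = c(A = -1)),
    compartments = c(c = "cytosol"),
    objective = list(reaction = "EX_A", direction = "maximize"))
  write_model(m, p, "sbml")
  b <- read_model(p)
  expect_equal(nrow(b$reactions), 1)
  expect_equal(nrow(b$metabolites), 1)
  expect_equal(b$reactions$lower_bound, -10)
})
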