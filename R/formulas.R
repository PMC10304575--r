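# Elemental formula handling (Hill notation) used by the mass-balance QC,
# the biomass builder and the carbon-efficiency statistic.

# Standard atomic weights (IUPAC 2021, rounded to 3 decimals) for the elements
# that occur in the models this package handles. One- or two-letter symbols
# outside this table are treated as pseudo-elements: they parse, but the
# formula is flagged unparseable-for-mass so balance checks can report it.
ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  Na = 22.990, K = 39.098, Cl = 35.45, Ca = 40.078, Mg = 24.305,
  Fe = 55.845, Zn = 65.38, Cu = 63.546, Mn = 54.938, Se = 78.971
)

#' Parse a Hill-notation chemical formula
#'
#' Splits a formula such as `"C6H12O6"` into named element counts. Element
#' symbols are one uppercase letter optionally followed by one lowercase
#' letter; a missing count means 1. Pseudo-elements (e.g. `"R"`, `"X"`)
#' are permitted so that generic residues can be carried through a model;
#' they are reported like any other symbol and flagged by
#' [formula_is_weighable()].
#'
#' @param formula A single formula string, or `NA`.
#' @return Named integer vector of element counts, or `NULL` when `formula`
#'   is `NA`/empty.
#' @examples
#' parse_formula("C6H12O6")
#' parse_formula("C27H46O")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() expects a single string")
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) {
    stop(sprintf("formula '%s' is not valid Hill notation", formula))
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  sym <- sub("[0-9]*$", "", parts)
  cnt <- sub("^[A-Za-z]+", "", parts)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  counts <- tapply(cnt, sym, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Test whether a formula has a defined molecular mass
#'
#' `TRUE` when every element symbol in the formula has a standard atomic
#' weight; pseudo-elements make a formula unweighable and exclude the
#' containing reaction from strict elemental balance.
#'
#' @param formula Formula string or `NA`.
#' @return Logical scalar; `NA` input gives `FALSE`.
#' @export
formula_is_weighable <- function(formula) {
  counts <- tryCatch(parse_formula(formula), error = function(e) NULL)
  if (is.null(counts)) return(FALSE)
  all(names(counts) %in% names(ATOMIC_WEIGHTS))
}

#' Molecular mass of a formula in g/mmol
#'
#' @param formula Hill-notation formula string.
#' @return Molar mass in g/mmol (numerically equal to g/mol × 1e-3 per mmol;
#'   the pipeline's flux unit is mmol/larva/day, so masses are kept in
#'   g/mmol throughout: mass in g = coefficient in mmol × molar mass).
#' @export
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (is.null(counts)) stop("cannot compute mass of an absent formula")
  unknown <- setdiff(names(counts), names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0) {
    stop(sprintf("formula '%s' contains pseudo-elements without atomic weight: %s",
                 formula, paste(unknown, collapse = ", ")))
  }
  sum(ATOMIC_WEIGHTS[names(counts)] * counts) / 1000
}

#' Carbon atoms per molecule
#'
#' Reads the C element count from a Hill-notation formula; used to weight
#' uptake and drain fluxes in the carbon-conversion-efficiency statistic.
#'
#' @param formula Hill-notation formula string.
#' @return Integer carbon count (0 when the formula holds no carbon).
#' @examples
#' carbon_count("C6H12O6")   # glucose, 6
#' carbon_count("C27H46O")   # cholesterol, 27
#' @export
carbon_count <- function(formula) {
  counts <- parse_formula(formula)
  if (is.null(counts)) stop("cannot count carbon in an absent formula")
  if (!"C" %in% names(counts)) return(0L)
  as.integer(counts[["C"]])
}

# Sum element counts over a named coefficient vector of formulas.
# Returns a named numeric vector of per-element totals (coef-weighted), or
# NULL when any formula is absent/unweighable.
sum_elements <- function(coefs, formulas) {
  total <- numeric(0)
  for (i in seq_along(coefs)) {
    f <- formulas[[i]]
    if (is.null(f) || is.na(f) || !nzchar(f)) return(NULL)
    counts <- tryCatch(parse_formula(f), error = function(e) NULL)
    if (is.null(counts)) return(NULL)
    for (el in names(counts)) {
      total[el] <- (if (el %in% names(total)) total[[el]] else 0) +
        coefs[[i]] * counts[[el]]
    }
  }
  total
}
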