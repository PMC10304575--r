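# Model readers/writers: COBRA JSON and the package's tabular CSV dialect,
# plus the format-dispatching entry points. SBML lives in io_sbml.R.

DEFAULT_BOUND <- 1000  # mmol/larva/day, COBRA-community default when a file omits bounds

#' Read a metabolic model from file
#'
#' Supported dialects: SBML Level 3 with the FBC package (`"sbml"`), COBRA
#' JSON (`"json"`), and a tabular CSV layout (`"tabular"`, see
#' [write_model()]). Bounds absent from a file default to +/-1000
#' mmol/larva/day.
#'
#' @param path File path (for `"tabular"`: a directory holding
#'   `model.csv`, `metabolites.csv`, `reactions.csv`).
#' @param format One of `"sbml"`, `"json"`, `"tabular"`; `"auto"` guesses
#'   from the file extension (`.xml`/`.sbml` -> sbml, `.json` -> json,
#'   directory -> tabular).
#' @return A validated [metabolic_model()].
#' @export
read_model <- function(path, format = c("auto", "sbml", "json", "tabular")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "tabular"
    else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml"
    else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else stop(sprintf("cannot guess model format from path '%s'", path))
  }
  if (!file.exists(path)) stop(sprintf("model file '%s' does not exist", path))
  switch(format,
         sbml = read_model_sbml(path),
         json = read_model_json(path),
         tabular = read_model_tabular(path))
}

#' Write a metabolic model to file
#'
#' The written file is readable by [read_model()] and yields a structurally
#' identical model (ids, stoichiometry, bounds, objective, GPR strings).
#' The tabular dialect is a directory of three CSVs: `metabolites.csv`
#' (id, name, compartment, formula, charge), `reactions.csv` (id, name,
#' equation such as `"2 A + B -> C"`, lower_bound, upper_bound, gpr,
#' subsystem), and `model.csv` (model id, compartments, objective, genes).
#'
#' @param model A validated `metabolic_model`.
#' @param path Output path (a directory for `"tabular"`).
#' @param format One of `"sbml"`, `"json"`, `"tabular"`.
#' @return Invisibly `path`.
#' @export
write_model <- function(model, path, format = c("sbml", "json", "tabular")) {
  format <- match.arg(format)
  validate_model(model)
  switch(format,
         sbml = write_model_sbml(model, path),
         json = write_model_json(model, path),
         tabular = write_model_tabular(model, path))
  invisible(path)
}

## ---- COBRA JSON ----------------------------------------------------------

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop(sprintf("JSON model '%s' lacks 'metabolites' or 'reactions'", path))
  }
  pick <- function(x, field, default) {
    v <- x[[field]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) default else v
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = as.character(pick(m, "name", m$id)),
               compartment = as.character(pick(m, "compartment", "c")),
               formula = as.character(pick(m, "formula", NA_character_)),
               charge = as.integer(pick(m, "charge", NA_integer_)),
               stringsAsFactors = FALSE)
  }))
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    data.frame(id = r$id,
               name = as.character(pick(r, "name", r$id)),
               lower_bound = as.numeric(pick(r, "lower_bound", -DEFAULT_BOUND)),
               upper_bound = as.numeric(pick(r, "upper_bound", DEFAULT_BOUND)),
               gpr = as.character(pick(r, "gene_reaction_rule", "")),
               subsystem = as.character(pick(r, "subsystem", "")),
               stringsAsFactors = FALSE)
  }))
  stoich <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) stop(sprintf("reaction '%s' has no metabolites", r$id))
    st
  })
  names(stoich) <- rxns$id
  obj_rxn <- NULL
  for (r in doc$reactions) {
    oc <- r$objective_coefficient
    if (!is.null(oc) && oc != 0) obj_rxn <- r$id
  }
  direction <- if (!is.null(doc$objective_direction)) doc$objective_direction else "maximize"
  if (is.null(obj_rxn)) stop(sprintf("JSON model '%s' declares no objective reaction", path))
  comps <- if (!is.null(doc$compartments) && length(doc$compartments) > 0) {
    unlist(doc$compartments)
  } else {
    stats::setNames(unique(mets$compartment), unique(mets$compartment))
  }
  genes <- vapply(doc$genes %||% list(), function(g) g$id, character(1))
  metabolic_model(id = doc$id %||% "model",
                  metabolites = mets, reactions = rxns, stoichiometry = stoich,
                  compartments = comps,
                  objective = list(reaction = obj_rxn, direction = direction),
                  genes = genes)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- as.integer(m$charge)
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    st <- model$stoichiometry[[r$id]]
    list(id = r$id, name = r$name,
         metabolites = as.list(st),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr, subsystem = r$subsystem,
         objective_coefficient = if (identical(r$id, model$objective$reaction)) 1 else 0)
  })
  doc <- list(id = model$id,
              metabolites = mets,
              reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g, name = g)),
              compartments = as.list(model$compartments),
              objective_direction = model$objective$direction,
              version = "1")
  # digits = I(17): 17 significant digits, enough for exact double round trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tabular CSV dialect -------------------------------------------------

# Render a stoichiometry map as an equation string, e.g. "2 A + B -> C".
# Pure exchange/demand reactions render with an empty side ("A -> ").
stoich_to_equation <- function(st) {
  fmt_side <- function(ids, coefs) {
    if (length(ids) == 0) return("")
    paste(ifelse(coefs == 1, ids, paste(format(coefs, digits = 17, trim = TRUE,
                                               scientific = FALSE), ids)),
          collapse = " + ")
  }
  subs <- st[st < 0]; prods <- st[st > 0]
  paste(fmt_side(names(subs), -unname(subs)), "->",
        fmt_side(names(prods), unname(prods)))
}

# Parse "2 A + B -> C" back into a named coefficient vector.
equation_to_stoich <- function(eq, reaction_id = "?") {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop(sprintf("reaction '%s': equation '%s' lacks a single '->'", reaction_id, eq))
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (term in terms) {
      toks <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(toks) == 1) {
        coef <- 1; met <- toks[1]
      } else if (length(toks) == 2) {
        coef <- suppressWarnings(as.numeric(toks[1])); met <- toks[2]
        if (is.na(coef)) stop(sprintf("reaction '%s': bad coefficient in term '%s'",
                                      reaction_id, term))
      } else {
        stop(sprintf("reaction '%s': cannot parse term '%s'", reaction_id, term))
      }
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs[setdiff(names(rhs), names(lhs))])
  for (met in intersect(names(rhs), names(lhs))) st[met] <- st[met] + rhs[[met]]
  st <- st[st != 0]
  if (length(st) == 0) stop(sprintf("reaction '%s': equation cancels to nothing", reaction_id))
  st
}

read_model_tabular <- function(path) {
  need <- file.path(path, c("model.csv", "metabolites.csv", "reactions.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0) {
    stop(sprintf("tabular model directory '%s' lacks: %s",
                 path, paste(basename(missing), collapse = ", ")))
  }
  info <- utils::read.csv(need[1], stringsAsFactors = FALSE)
  mets <- utils::read.csv(need[2], stringsAsFactors = FALSE,
                          colClasses = c(formula = "character"))
  rxn_tab <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  mets$formula[is.na(mets$formula) | mets$formula == ""] <- NA_character_
  mets$charge <- suppressWarnings(as.integer(mets$charge))
  if (is.null(rxn_tab$lower_bound)) rxn_tab$lower_bound <- -DEFAULT_BOUND
  if (is.null(rxn_tab$upper_bound)) rxn_tab$upper_bound <- DEFAULT_BOUND
  rxn_tab$lower_bound[is.na(rxn_tab$lower_bound)] <- -DEFAULT_BOUND
  rxn_tab$upper_bound[is.na(rxn_tab$upper_bound)] <- DEFAULT_BOUND
  rxn_tab$gpr[is.na(rxn_tab$gpr)] <- ""
  rxn_tab$subsystem[is.na(rxn_tab$subsystem)] <- ""
  stoich <- lapply(seq_len(nrow(rxn_tab)), function(i) {
    equation_to_stoich(rxn_tab$equation[i], rxn_tab$id[i])
  })
  names(stoich) <- rxn_tab$id
  field <- function(key) {
    v <- info$value[info$key == key]
    if (length(v) == 0) NA_character_ else v
  }
  comp_tokens <- strsplit(field("compartments"), ";", fixed = TRUE)[[1]]
  comps <- character(0)
  for (tok in comp_tokens) {
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    comps[kv[1]] <- if (length(kv) > 1) kv[2] else kv[1]
  }
  genes <- field("genes")
  genes <- if (is.na(genes) || !nzchar(genes)) character(0)
           else strsplit(genes, ";", fixed = TRUE)[[1]]
  metabolic_model(
    id = field("id"),
    metabolites = mets[, c("id", "name", "compartment", "formula", "charge")],
    reactions = rxn_tab[, c("id", "name", "lower_bound", "upper_bound",
                            "gpr", "subsystem")],
    stoichiometry = stoich,
    compartments = comps,
    objective = list(reaction = field("objective_reaction"),
                     direction = field("objective_direction")),
    genes = genes)
}

write_model_tabular <- function(model, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  num <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  info <- data.frame(
    key = c("id", "compartments", "objective_reaction", "objective_direction", "genes"),
    value = c(model$id,
              paste(sprintf("%s=%s", names(model$compartments), model$compartments),
                    collapse = ";"),
              model$objective$reaction, model$objective$direction,
              paste(model$genes, collapse = ";")),
    stringsAsFactors = FALSE)
  utils::write.csv(info, file.path(path, "model.csv"), row.names = FALSE)
  utils::write.csv(model$metabolites, file.path(path, "metabolites.csv"),
                   row.names = FALSE)
  rxn_tab <- model$reactions
  rxn_tab$equation <- vapply(model$stoichiometry[rxn_tab$id],
                             stoich_to_equation, character(1))
  rxn_tab$lower_bound <- num(rxn_tab$lower_bound)
  rxn_tab$upper_bound <- num(rxn_tab$upper_bound)
  utils::write.csv(rxn_tab[, c("id", "name", "equation", "lower_bound",
                               "upper_bound", "gpr", "subsystem")],
                   file.path(path, "reactions.csv"), row.names = FALSE)
}
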