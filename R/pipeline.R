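# Configuration-driven experiment driver: loads or generates a model,
# applies the diet, runs QC, the growth-rate perturbation scenarios, the
# fatty-acid FVA and the carbon-efficiency comparison, and writes a
# reproducible report bundle (CSV tables + a deterministic JSON summary +
# a run log). The numbered scripts under analysis/ are thin wrappers over
# the same functions.

#' Build an experiment configuration
#'
#' @param model `"synthetic"`, or a path to a model file readable by
#'   [read_model()].
#' @param format Model file format for [read_model()] (ignored for
#'   synthetic).
#' @param synthetic A [synthetic_network_params()] used when
#'   `model == "synthetic"`; its seed is overridden by `seed`.
#' @param diet `NULL` for [reference_diet()], or a path to a two-column CSV
#'   (`exchange_id`, `mmol_per_larva_day`).
#' @param scenarios Character vector of perturbation scenarios (see
#'   [run_perturbation_experiment()]); entries of the form
#'   `"doubled_single_AA:Valine"` carry the amino acid after the colon.
#' @param fva_fraction Fraction of optimum maintained in FVA.
#' @param eaa Essential amino-acid name set.
#' @param fa_drains Drain reaction ids for the synthesis-rate and CCE
#'   stages; `NULL` autodetects `DM_<fatty acid>` drains.
#' @param run_qc Run the QC stage (the blocked-reaction scan is the
#'   pipeline's most expensive step).
#' @param out_dir Output directory.
#' @param seed Integer seed (forwarded to the synthetic generator).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(model = "synthetic",
                              format = "auto",
                              synthetic = synthetic_network_params(),
                              diet = NULL,
                              scenarios = c("doubled_glucose", "doubled_EAA",
                                            "doubled_single_AA:Valine"),
                              fva_fraction = 0.9,
                              eaa = essential_amino_acids(),
                              fa_drains = NULL,
                              run_qc = TRUE,
                              out_dir = tempfile("larvaflux_run_"),
                              seed = 7L) {
  if (length(scenarios) == 0) stop("scenarios must be non-empty")
  if (!(fva_fraction > 0 && fva_fraction <= 1)) stop("fva_fraction must be in (0, 1]")
  structure(list(model = model, format = format, synthetic = synthetic,
                 diet = diet, scenarios = scenarios,
                 fva_fraction = fva_fraction, eaa = eaa,
                 fa_drains = fa_drains, run_qc = isTRUE(run_qc),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognized keys mirror the [experiment_config()] arguments; the
#' `synthetic:` block is passed to [synthetic_network_params()].
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_network_params, y$synthetic %||% list())
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  do.call(experiment_config, args)
}

#' Run the full dietary-perturbation experiment pipeline
#'
#' Stages: model acquisition, diet application, quality control, reference
#' FBA, growth-rate changes per scenario, fatty-acid synthesis FVA under
#' reference and doubled-glucose diets, and the carbon-conversion-
#' efficiency comparison. Every stage failure aborts with a stage-named
#' error. All outputs are written under `config$out_dir`; the JSON summary
#' is deterministic, so identical configurations (including seed) produce
#' byte-identical summaries.
#'
#' @param config An [experiment_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  unlink(log_path)
  logline("larvaflux pipeline")
  logline("seed: %d", config$seed)
  logline("solver: built-in bounded-variable simplex, tol 1e-9")

  model <- stage("model", {
    if (identical(config$model, "synthetic")) {
      params <- config$synthetic
      params$seed <- config$seed
      generate_network(params)
    } else {
      read_model(config$model, config$format)
    }
  })
  logline("model: %s (%d metabolites, %d reactions)", model$id,
          nrow(model$metabolites), nrow(model$reactions))

  bounds <- stage("diet", {
    if (is.null(config$diet)) {
      params <- if (identical(config$model, "synthetic")) {
        p <- config$synthetic; p$seed <- config$seed; p
      } else synthetic_network_params()
      reference_diet(params)
    } else {
      tab <- utils::read.csv(config$diet, stringsAsFactors = FALSE)
      exchange_bounds(stats::setNames(tab$mmol_per_larva_day, tab$exchange_id))
    }
  })
  utils::write.csv(data.frame(exchange_id = names(bounds),
                              mmol_per_larva_day = as.numeric(bounds)),
                   file.path(config$out_dir, "diet_bounds.csv"),
                   row.names = FALSE)

  fa_drains <- config$fa_drains
  if (is.null(fa_drains)) {
    fa_drains <- grep("^DM_c\\d+$", model$reactions$id, value = TRUE)
  }

  qc <- NULL
  if (config$run_qc) {
    qc <- stage("qc", qc_report(model))
    utils::write.csv(qc_report_row(qc), file.path(config$out_dir, "qc.csv"),
                     row.names = FALSE)
    logline("qc: dead-end %.2f%%, blocked %.2f%%, unbalanced %.2f%%, exchange %.2f%%",
            qc$pct_dead_end_metabolites, qc$pct_blocked_reactions,
            qc$pct_unbalanced_reactions, qc$pct_exchange_reactions)
  }

  constrained <- stage("diet", apply_diet(model, bounds))
  reference <- stage("fba", fba(constrained))
  logline("reference FBA: %s, objective %.6g", reference$status,
          reference$objective_value)
  if (reference$status != "optimal") {
    stop("pipeline stage 'fba' failed: reference diet not optimal")
  }
  utils::write.csv(data.frame(reaction = names(reference$fluxes),
                              flux = as.numeric(reference$fluxes)),
                   file.path(config$out_dir, "fba_reference.csv"),
                   row.names = FALSE)

  growth <- stage("scenarios", {
    rows <- lapply(config$scenarios, function(sc) {
      parts <- strsplit(sc, ":", fixed = TRUE)[[1]]
      res <- run_perturbation_experiment(
        model, bounds, scenario = parts[1],
        single_aa = if (length(parts) > 1) parts[2] else NULL,
        fva_fraction = config$fva_fraction, eaa = config$eaa)
      logline("scenario %s: %+.2f%%", sc, res$growth_change_percent)
      data.frame(scenario = sc,
                 reference_growth = res$reference$objective_value,
                 perturbed_growth = res$perturbed$objective_value,
                 growth_change_percent = round(res$growth_change_percent, 2),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  utils::write.csv(growth, file.path(config$out_dir, "growth_changes.csv"),
                   row.names = FALSE)

  fa_tab <- cce_tab <- NULL
  if (length(fa_drains) > 0) {
    fa_tab <- stage("fva", {
      glc_bounds <- if ("EX_glc_e" %in% names(bounds)) {
        scale_uptake(bounds, "EX_glc_e", 2)
      } else bounds
      ref <- fva(apply_diet(model, bounds), fraction = config$fva_fraction,
                 reactions = fa_drains)$ranges
      dbl <- fva(apply_diet(model, glc_bounds), fraction = config$fva_fraction,
                 reactions = fa_drains)$ranges
      rbind(cbind(diet = "reference", ref),
            cbind(diet = "doubled_glucose", dbl))
    })
    utils::write.csv(fa_tab, file.path(config$out_dir, "fa_fva.csv"),
                     row.names = FALSE)
    cce_tab <- stage("cce", {
      glc_bounds <- if ("EX_glc_e" %in% names(bounds)) {
        scale_uptake(bounds, "EX_glc_e", 2)
      } else bounds
      rbind(cce_experiment(model, bounds, fa_drains,
                           fraction = config$fva_fraction,
                           diet_label = "reference"),
            cce_experiment(model, glc_bounds, fa_drains,
                           fraction = config$fva_fraction,
                           diet_label = "doubled_glucose"))
    })
    utils::write.csv(cce_tab, file.path(config$out_dir, "cce.csv"),
                     row.names = FALSE)
  }

  summary <- list(
    model = model$id,
    seed = config$seed,
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    reference_growth = reference$objective_value,
    qc = if (!is.null(qc)) qc_report_row(qc) else NULL,
    growth_changes = growth,
    fatty_acid_fva = fa_tab,
    cce = cce_tab)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  logline("done")
  invisible(summary)
}
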