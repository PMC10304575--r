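#!/usr/bin/env Rscript
# Model quality control: dead-end metabolites, blocked reactions,
# elemental balance and exchange share of the synthetic network, in the
# cross-model comparison layout.

suppressPackageStartupMessages(library(larvaflux))
dir.create("results", showWarnings = FALSE)

model <- generate_network(synthetic_network_params(seed = 7))
qc <- qc_report(model)
print(qc)

message(sprintf("dead ends: %s",
                paste(qc$dead_end_metabolites, collapse = ", ")))
message(sprintf("%d blocked, %d unbalanced (exchanges + biomass), %d exchange reactions",
                length(qc$blocked_reactions), length(qc$unbalanced_reactions),
                length(qc$exchange_reactions)))

write.csv(qc_report_row(qc), "results/qc.csv", row.names = FALSE)
jsonlite::write_json(
  qc[c("model_id", "n_metabolites", "n_reactions", "n_genes",
       "pct_dead_end_metabolites", "pct_blocked_reactions",
       "pct_unbalanced_reactions", "pct_exchange_reactions",
       "dead_end_metabolites", "blocked_reactions")],
  "results/qc.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/qc.csv, results/qc.json")
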