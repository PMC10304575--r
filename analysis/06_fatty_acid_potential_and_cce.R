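#!/usr/bin/env Rscript
# In-silico experiment set (b): fatty-acid synthesis-rate potential (FVA at
# 90% of the growth optimum) and dietary carbon conversion efficiency,
# reference diet vs doubled glucose.

suppressPackageStartupMessages(library(larvaflux))
dir.create("results", showWarnings = FALSE)

model <- generate_network(synthetic_network_params(seed = 7))
diet <- reference_diet()
drains <- grep("^DM_c\\d+$", model$reactions$id, value = TRUE)
dbl <- scale_uptake(diet, "EX_glc_e", 2)

ref_fva <- fva(apply_diet(model, diet), fraction = 0.9, reactions = drains)
dbl_fva <- fva(apply_diet(model, dbl), fraction = 0.9, reactions = drains)
fa_tab <- merge(ref_fva$ranges, dbl_fva$ranges, by = "reaction",
                suffixes = c("_reference", "_doubled_glucose"))
fa_tab$increase_pct <- round(100 * (fa_tab$max_flux_doubled_glucose /
                                      fa_tab$max_flux_reference - 1), 2)
for (i in seq_len(nrow(fa_tab))) {
  message(sprintf("%-8s max synthesis %.5f -> %.5f mmol/larva/day (+%.1f%%)",
                  fa_tab$reaction[i], fa_tab$max_flux_reference[i],
                  fa_tab$max_flux_doubled_glucose[i], fa_tab$increase_pct[i]))
}
write.csv(fa_tab, "results/fa_fva.csv", row.names = FALSE)

cce <- rbind(
  cce_experiment(model, diet, drains, diet_label = "reference"),
  cce_experiment(model, dbl, drains, diet_label = "doubled_glucose"))
write.csv(cce, "results/cce.csv", row.names = FALSE)
message(sprintf(
  "Mean carbon conversion efficiency: %.1f%% (reference) vs %.1f%% (doubled glucose)",
  mean(cce$cce_efficiency[cce$diet == "reference"]),
  mean(cce$cce_efficiency[cce$diet == "doubled_glucose"])))
message("On this stand-in network the extra glucose carbon is routed almost ",
        "fully into the fatty-acid drains, so efficiency rises; a saturated ",
        "network (as in the published reconstruction) shows the opposite.")
message("wrote results/fa_fva.csv, results/cce.csv")
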