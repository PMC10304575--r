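#!/usr/bin/env Rscript
# Fatty-acid composition bookkeeping: saturation classes and the coverage
# of the six TAG-modeled species, from the measured larval profile.

suppressPackageStartupMessages(library(larvaflux))
dir.create("results", showWarnings = FALSE)

profile <- larva_fatty_acid_profile()
bk <- fatty_acid_bookkeeping()

message(sprintf(
  "Saturated fatty acids (C12:0+C14:0+C16:0+C18:0): %.2f g/100 g fat -> %d%%",
  bk$saturated_g, bk$saturated_pct))
message(sprintf(
  "Six TAG-modeled species jointly cover %.2f g/100 g fat (>= 90%% of the profile)",
  bk$modeled_coverage_g))
message(sprintf("Headline shares: lauric %d%%, oleic %d%%, linoleic (PUFA) %d%%",
                bk$lauric_pct, bk$oleic_pct, bk$polyunsaturated_pct))
message(sprintf(
  "Monounsaturated sum from the table: %.2f g/100 g -> %d%%",
  bk$monounsaturated_g, bk$monounsaturated_pct))

write.csv(profile, "results/fatty_acid_profile.csv", row.names = FALSE)
write.csv(data.frame(statistic = names(unlist(bk)), value = unlist(bk)),
          "results/fatty_acid_bookkeeping.csv", row.names = FALSE)
message("wrote results/fatty_acid_profile.csv, results/fatty_acid_bookkeeping.csv")
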