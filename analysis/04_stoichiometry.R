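#!/usr/bin/env Rscript
# Stage 4: single-cell C:N:P stoichiometry from SEM-EDS atom%.
#
# Per-cell atomic ratios with a population summary, set against the
# Redfield reference (C:N 6.6, C:P 116, N:P 16). Glacier ice algae sit far
# above Redfield in C:N and C:P — low nutrient quota, not necessarily
# nutrient limitation.

suppressPackageStartupMessages(library(glacierSIP))

eds <- read_eds_table("results/synthetic/eds.csv")
st <- stoichiometry_from_eds(eds)

write.csv(st$per_cell, "results/stoichiometry_cells.csv", row.names = FALSE)
write.csv(st$summary, "results/stoichiometry_summary.csv", row.names = FALSE)

for (i in seq_len(nrow(st$summary))) {
  s <- st$summary[i, ]
  message(sprintf("%s = %.1f +/- %.1f (n = %d; Redfield %.1f, %.1fx)",
                  s$ratio, s$mean, s$sd, s$n, s$redfield, s$mean / s$redfield))
}
message("wrote results/stoichiometry_*.csv")
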