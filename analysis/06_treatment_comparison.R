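#!/usr/bin/env Rscript
# Stage 6: does nutrient amendment change single-cell C-based growth?
#
# Kruskal-Wallis omnibus test across treatments on active cells at T2,
# followed by Holm-adjusted pairwise rank comparisons with a compact
# letter display. Inactive cells are excluded, as they carry no rate
# signal.

suppressPackageStartupMessages(library(glacierSIP))

rates <- read.csv("results/cell_rates.csv")
t2 <- rates[rates$timepoint == "T2" & rates$active & !is.na(rates$mu_c), ]

cg <- compare_groups(t2$mu_c, t2$treatment)
message(sprintf("Kruskal-Wallis: chi-squared = %.2f, df = %d, p = %.3g",
                cg$statistic, cg$df, cg$p_value))
for (i in seq_len(nrow(cg$pairwise))) {
  message(sprintf("  %s vs %s: p = %.3f (Holm %.3f)",
                  cg$pairwise$group1[i], cg$pairwise$group2[i],
                  cg$pairwise$p[i], cg$pairwise$p_holm[i]))
}
message("letters: ", paste(names(cg$letters), cg$letters, sep = "=",
                           collapse = ", "))

out <- data.frame(statistic = cg$statistic, df = cg$df, p = cg$p_value)
write.csv(out, "results/treatment_comparison.csv", row.names = FALSE)
write.csv(cg$pairwise, "results/treatment_pairwise.csv", row.names = FALSE)
message("wrote results/treatment_comparison.csv")
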