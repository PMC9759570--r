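#!/usr/bin/env Rscript
# Stage 5 — systematic correlation analysis.
#
# Merges the per-animal feature table with the per-animal AUCs from the
# PK fits and computes the full Pearson correlation matrix with
# Benjamini-Hochberg-adjusted significance stars (joint adjustment over
# all feature pairs), plus the headline pairwise correlations between
# steatosis severity and CYP activity with 95% confidence intervals and
# strength labels.

library(steatoPK)

features <- read_features("results/features.csv")
pk <- read.csv("results/pk_parameters.csv")

auc_wide <- reshape(pk[, c("animal_id", "analyte", "auc_ng_h_ml")],
                    idvar = "animal_id", timevar = "analyte",
                    direction = "wide")
names(auc_wide) <- sub("auc_ng_h_ml.", "auc_", names(auc_wide))
merged <- merge(features, auc_wide, by = "animal_id")
write_features(merged, "results/features_with_auc.csv")

res <- correlation_matrix(merged)
write.csv(res$r, "results/correlation_r.csv")
write.csv(res$p_adj, "results/correlation_p_adj.csv")
write.csv(res$stars, "results/correlation_stars.csv")
print(res)

message("\nheadline pairwise correlations:")
for (pair in list(c("lipid_droplet_pct", "cyp1a_erod"),
                  c("lipid_droplet_pct", "cyp2e1_pnph"),
                  c("macro_pct", "auc_midazolam"))) {
  ct <- pearson_with_ci(merged[[pair[1]]], merged[[pair[2]]])
  message(sprintf("  %s vs %s: r = %.2f [%.2f, %.2f], p = %.3g (%s)",
                  pair[1], pair[2], ct$r, ct$ci95[1], ct$ci95[2],
                  ct$p_two_tailed, ct$strength_label))
}
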