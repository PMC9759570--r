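#!/usr/bin/env Rscript
# Stage 4 — steatosis surface aggregation and grading.
#
# Emulates the tile classifier downstream: for each animal, draws a
# classified tile grid matching its configured surfaces, aggregates tiles
# into micro/macro/total surface percentages (lumen excluded), grades
# severity by the 33/66% convention, and reports the per-group
# micro:macro ratio from the group mean surfaces.

library(steatoPK)

seed <- 20260922L
features <- read_features("results/features.csv")

surf_rows <- lapply(seq_len(nrow(features)), function(i) {
  row <- features[i, ]
  grid <- generate_tile_grid(
    steatosis_surfaces(row$micro_pct, row$macro_pct),
    n_tiles = 4000, seed = seed + i)
  surf <- aggregate_tiles(grid)
  data.frame(animal_id = row$animal_id, group = row$group,
             micro_pct = surf$micro_pct, macro_pct = surf$macro_pct,
             total_steatotic_pct = surf$total_steatotic_pct,
             grade = severity_grade(surf$total_steatotic_pct))
})
surfaces <- do.call(rbind, surf_rows)
write.csv(surfaces, "results/steatosis_surfaces.csv", row.names = FALSE)

for (g in unique(surfaces$group)) {
  sub <- surfaces[surfaces$group == g, ]
  ratio <- micro_macro_ratio(mean(sub$micro_pct), mean(sub$macro_pct))
  message(sprintf(
    "%s: micro %.1f%%, macro %.1f%%, ratio %.1f:1; grades: %s", g,
    mean(sub$micro_pct), mean(sub$macro_pct), ratio,
    paste(sprintf("%s x%d", names(table(sub$grade)), table(sub$grade)),
          collapse = ", ")))
}

# whole-liver summary for one animal from per-lobe measurements
lobes <- list(
  steatosis_surfaces(48, 21), steatosis_surfaces(52, 18),
  steatosis_surfaces(44, 25), steatosis_surfaces(50, 20))
whole <- mean_across_lobes(lobes, areas = c(4, 2, 1.5, 1))
message(sprintf(
  "lobe-averaged example: micro %.1f%%, macro %.1f%%, total %.1f%% (%s)",
  whole$micro_pct, whole$macro_pct, whole$total_steatotic_pct,
  severity_grade(whole$total_steatotic_pct)))
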