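#!/usr/bin/env Rscript
# Stage 1 — simulate the study's measurements.
#
# Draws the synthetic cohort from the calibrated defaults: 6 animals per
# dietary group (control, 2-week HF-diet, 4-week HF-diet), a per-animal
# feature table (steatosis surfaces, triglycerides, CYP activities) and
# drug-cocktail concentration time courses at the ten scheduled sampling
# times over six hours, with additive Gaussian measurement noise.

library(steatoPK)

seed <- 20260922L
dir.create("results", showWarnings = FALSE)

cfg <- default_config()
message("Simulating cohort: ", cfg$n_per_group, " animals/group, seed ",
        seed)

features <- generate_features(cfg, seed = seed)
write_features(features, "results/features.csv")
message("features.csv: ", nrow(features), " animals, ",
        ncol(features) - 2, " features")

timecourses <- generate_timecourses(cfg, seed = seed)
write_timecourses(timecourses, "results/timecourses.csv")
message("timecourses.csv: ", length(timecourses),
        " series of 10 points (",
        length(unique(vapply(timecourses, function(s) s$analyte, ""))),
        " analytes)")
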