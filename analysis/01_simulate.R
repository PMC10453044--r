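#!/usr/bin/env Rscript

# Stage 1 — synthetic 90K-style experiment.
#
# Generates the study's default conditions: a 900-marker panel over the
# 6A/6B/6D subgenomes (60 Mb each), the euploid parent Chara plus a second
# backcross seed stock carrying biotype discordance at 2% of markers, one
# homozygous mutant and one backcross F1 per deletion (the three mapped
# intervals are the default ground truth), and a 96-line unrelated panel.
# Writes the marker map, the intensity table and the truth record under
# results/run/.

library(hibdel)

cfg <- sim_config(n_markers = 900, seed = 20260919L)
sim <- simulate_experiment(cfg)

dir.create("results/run", recursive = TRUE, showWarnings = FALSE)
write_marker_map(sim$markers, "results/run/markers.csv")
write_intensities(sim$intensities, "results/run/intensities.csv")
write_truth(sim$truth, "results/run/truth.json")

message(sprintf("markers: %d (%.0f%% multi-site), samples: %d, biotype markers: %d",
                nrow(sim$markers), 100 * mean(n_sites(sim$markers) > 1),
                length(unique(sim$intensities$sample_id)),
                length(sim$truth$biotype_markers)))
message("true deletions:")
print(sim$truth$deletions)
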