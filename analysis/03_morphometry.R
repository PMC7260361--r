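#!/usr/bin/env Rscript
# Step 3: ultrastructure features, their correlation with frost fitness,
# and group-versus-rest contrasts.

suppressPackageStartupMessages(library(dictyfit))
in_dir <- "results/simulated"
out_dir <- "results/morphometry"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cells <- read.csv(file.path(in_dir, "morphometry_cells.csv"))
fit <- read.csv(file.path(out_dir, "../fitness/relative_fitness.csv"))

feats <- species_feature_summary(cells)
write.csv(feats, file.path(out_dir, "species_features.csv"), row.names = FALSE)

fc <- feature_fitness_correlation(feats, fit, condition = "m20C_wet")
write.csv(fc, file.path(out_dir, "feature_fitness_correlation.csv"),
          row.names = FALSE)

contrast <- group_feature_contrast(feats[feats$form == "spore" &
                                           feats$taxon_group != "minor", ])
write.csv(contrast, file.path(out_dir, "group_feature_contrast.csv"),
          row.names = FALSE)

cat("Features correlated with wet-frost fitness (p < 0.05):\n")
sig <- fc[fc$direction != "ns", ]
for (i in seq_len(nrow(sig))) {
  cat(sprintf("  %-30s rho = %+.2f (%s)\n", sig$feature[i], sig$rho[i],
              sig$direction[i]))
}
wall <- contrast[contrast$feature == "wall_total_width", ]
cat("Wall-width group flags:",
    paste(sprintf("grp%s=%s", wall$group, wall$flag), collapse = ", "), "\n")
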