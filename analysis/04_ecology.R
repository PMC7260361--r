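#!/usr/bin/env Rscript
# Step 4: climate-zone matrix and climate-fitness correlations.
#
# Builds the per-group percentage matrix of coldest isolation climates
# from the broad ecology roster, and correlates the survival panel's
# coldest/warmest climate ranks with spore fitness per storage condition.

suppressPackageStartupMessages(library(dictyfit))
in_dir <- "results/simulated"
out_dir <- "results/ecology"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

eco85 <- read.csv(file.path(in_dir, "ecology_roster85.csv"))
climate <- read.csv(file.path(in_dir, "climate_panel.csv"))
fit <- read.csv("results/fitness/relative_fitness.csv")

t1 <- build_table1(eco85)
write.csv(t1, file.path(out_dir, "coldest_climate_matrix.csv"))
cat("Coldest-climate percentage matrix (rows = taxon groups):\n")
print(t1)

rows <- list()
for (cond in unique(fit$condition)) {
  for (extreme in c("coldest", "warmest")) {
    r <- climate_fitness_correlation(climate, fit, cond, extreme)
    rows[[length(rows) + 1]] <- data.frame(condition = cond,
                                           extreme = extreme, rho = r$rho,
                                           p_value = r$p_value, n = r$n)
  }
}
cors <- do.call(rbind, rows)
write.csv(cors, file.path(out_dir, "climate_fitness_correlation.csv"),
          row.names = FALSE)
cat("\nClimate-fitness Spearman correlations (spore fitness):\n")
print(cors, digits = 3)
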