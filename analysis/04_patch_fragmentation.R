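#!/usr/bin/env Rscript
# Patch fragmentation at fixed total food area: the two-patch food surface
# S = 2*pi*25^2 is redistributed into 1..64 randomly placed patches of
# radius R' = sqrt(S/(N*pi)), the inward-turn bias profile is rescaled by
# R'/R, and residence and patch-visitation fractions are tracked as the food
# becomes more fragmented.  Residence falls with fragmentation; richer food
# (yeast) retains larvae better than sucrose at every patch number, while
# sucrose explorers visit a larger share of the available patches.
#
# Writes results/04_fragmentation.csv

suppressPackageStartupMessages(library(larvaforage))
set.seed(105)
dir.create("results", showWarnings = FALSE)

profile <- read_bias_profile(system.file("extdata",
                                         "bias_profile_synthetic.yaml",
                                         package = "larvaforage"))
grid <- c(1, 2, 4, 8, 16, 32, 64)
rows <- list()
for (genotype in c("rover", "sitter")) {
  for (substrate in c("sucrose", "yeast")) {
    res <- fragmentation_experiment(genotype, substrate,
                                    n_patches_grid = grid,
                                    n_larvae = 12, n_runs = 8,
                                    bias = profile)
    res$genotype <- genotype
    res$patch_substrate <- substrate
    rows[[length(rows) + 1]] <- res
    cat(sprintf("%s / %s: residence %s%%\n", genotype, substrate,
                paste(sprintf("%.1f", 100 * res$mean_fraction_inside),
                      collapse = " ")))
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/04_fragmentation.csv", row.names = FALSE)
cat("\nwrote results/04_fragmentation.csv\n")
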