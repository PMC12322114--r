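#!/usr/bin/env Rscript
# Step 1 — simulate the synthetic study world.
#
# Generates a seeded synthetic input bundle at the study scale (64x64 km
# target grid, 3 NUTS1 units each split into 2 NUTS2 units, 16 crops,
# years 2010-2012, constant equipped-area change ratio) and serializes it
# under results/world/. The bundle carries per-cell ground truth, so every
# later step can be checked against exact expected values.

library(irrigrid)

seed <- 101L
cfg <- world_config(grid_height = 64, grid_width = 64, n_nuts1 = 3,
                    nuts2_per_nuts1 = 2, n_crops = 16, years = 2010:2012,
                    ratio_mode = "constant", seed = seed)
bundle <- run_simulate(cfg, "results/world")

cat(sprintf("world: %d cells, %d NUTS2 regions, %d crops, %d years\n",
            prod(dim(bundle$region_raster$index)),
            length(bundle$region_raster$region_ids),
            bundle$config$n_crops, length(bundle$config$years)))
cat(sprintf("total true irrigated area %d: %.1f ha\n",
            cfg$years[1],
            sum(stack_total(bundle$truth_aai[[1]]), na.rm = TRUE)))
cat("serialized to results/world/\n")
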