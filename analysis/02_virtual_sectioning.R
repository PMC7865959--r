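#!/usr/bin/env Rscript
# Stage 2: cut virtual TEM sections through the simulated block.
#
# Recreates the stage-1 block deterministically (the CSV schema carries no
# cap orientations, so the generator is re-run with the same seed), then
# sections it into 75 micrograph fields of ~25 um^2 (total ~1900 um^2) with
# 65 nm slabs, and writes the per-profile measurement table.

library(spinestereo)

SEED <- 20260926
dir.create("results", showWarnings = FALSE)

params <- spine_params()
block <- place_in_volume(generate_population(380, params, seed = SEED + 1),
                         c(10, 10, 1.9), seed = SEED + 2)

planes <- section_planes(75, block$extent, sqrt(1900 / 75),
                         thickness = 0.065, seed = SEED + 3)
sect <- section_volume(block, planes, section_criteria(), seed = SEED + 4)
print(sect)

pr <- sect$profiles
cat(sprintf("  mean SAL %.3f um, mean PSD_L %.3f um, mean head area %.3f um^2\n",
            mean(pr$sal_length_um), mean(pr$psd_length_um),
            mean(pr$head_area_um2)))

write_profile_table(sect, "results/profiles_2d.csv")
utils::write.csv(planes, "results/micrographs.csv", row.names = FALSE)
cat("wrote results/profiles_2d.csv, results/micrographs.csv\n")
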