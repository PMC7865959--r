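#!/usr/bin/env Rscript
# Stage 1: simulate the ground-truth tissue.
#
# Builds (a) a reference cohort of 340 reconstructed spine heads drawn from
# the calibrated generator (volumes 0.004-0.300 um^3, mean 0.066; SAS
# coupled to volume^(2/3)) and (b) a 190 um^3 neuropil block at 2
# synapses/um^3 in which those statistics hold, writing both as CSV under
# results/. Everything downstream is deterministic given SEED.

library(spinestereo)

SEED <- 20260926
dir.create("results", showWarnings = FALSE)

params <- spine_params()
cat("Calibrated generator:\n")
cat(sprintf("  lognormal(meanlog = %.4f, sdlog = %.2f) truncated to [%.3f, %.3f] um^3\n",
            params$v_meanlog, params$v_sdlog, params$v_min, params$v_max))
cat(sprintf("  SAS = %.4f * V^(2/3) * exp(eps), sd(eps) = %.2f\n",
            params$sas_c, params$sas_sigma))

cohort <- generate_population(340, params, seed = SEED)
heads <- cohort[!cohort$on_shaft, ]
cat(sprintf("\nCohort of %d synapses (%d on shafts):\n",
            nrow(cohort), sum(cohort$on_shaft)))
s <- rbind(summarize_values(heads$head_volume_um3, "head volume", "um^3"),
           summarize_values(heads$sas_um2, "SAS", "um^2"))
print(s, digits = 3)
cat(sprintf("  %.1f%% of head volumes are below 0.1 um^3\n",
            100 * mean(heads$head_volume_um3 < 0.1)))

block <- place_in_volume(generate_population(380, params, seed = SEED + 1),
                         c(10, 10, 1.9), seed = SEED + 2)
print(block)

write_spine_table(cohort, "results/spines_cohort_3d.csv")
write_spine_table(block, "results/spines_block_3d.csv")
utils::write.csv(s, "results/cohort_summary.csv", row.names = FALSE)
cat("\nwrote results/spines_cohort_3d.csv, results/spines_block_3d.csv,",
    "results/cohort_summary.csv\n")
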