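#!/usr/bin/env Rscript
# Stage 1: generate the synthetic boom-bust waterbird system (demo preset:
# 12 species, 60 planning units, 30 years) and write its tables under
# results/. Downstream stages read these files, so the whole workflow is
# reproducible from this seed alone.

suppressPackageStartupMessages(library(wetlandprior))

seed <- 42
params <- scenario_preset("demo", seed = seed)
covariates <- simulate_covariates(params, seed = seed + 1)
sim <- simulate_counts(params, covariates, seed = seed + 2)

dir.create("results", showWarnings = FALSE)
write_covariates_csv(covariates, "results/covariates.csv")
write_abundance_csv(sim$counts, "results/counts.csv")
write.csv(sim$pu, "results/pu.csv", row.names = FALSE)
write.csv(sim$truth, "results/truth.csv", row.names = FALSE)

tot <- tapply(sim$counts$count, sim$counts$year, sum)
cat(sprintf("simulated %d species x %d PUs x %d years (seed %d)\n",
            params$n_species, params$n_pus, params$n_years, seed))
cat(sprintf("yearly totals: %d-%d (CV %.2f) -- boom/bust contrast of %.0fx\n",
            min(tot), max(tot), sd(tot) / mean(tot), max(tot) / min(tot)))
cat(sprintf("designated roles: %d refuge, %d breeding, %d both, %d neither\n",
            sum(sim$truth$role == "refuge"), sum(sim$truth$role == "breeding"),
            sum(sim$truth$role == "both"), sum(sim$truth$role == "neither")))
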