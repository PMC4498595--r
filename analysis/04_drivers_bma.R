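#!/usr/bin/env Rscript
# Stage 4: water-availability drivers. (a) Gaussian BIC model averaging of
# the annual number of PUs required for the 80% target on standardised
# predictors (log flow, year, regional rainfall, climate index) after the
# VIF collinearity screen; (b) per-PU Poisson model averaging of yearly
# selection counts against log flow, for PUs selected in at least five
# years, giving each wetland's sign of flow dependence.

suppressPackageStartupMessages(library(wetlandprior))

covariates <- read_covariates_csv("results/covariates.csv")
n_pus <- read.csv("results/annual_n_pus.csv")
irsc_df <- read.csv("results/annual_irsc.csv", check.names = FALSE)
irsc <- as.matrix(irsc_df[, -1])
rownames(irsc) <- irsc_df$pu_id

ann <- bma_annual_pus(n_pus, covariates)
if (nrow(ann$screen$trace))
  cat("VIF screen dropped:",
      paste(sprintf("%s (%.1f)", ann$screen$trace$column,
                    ann$screen$trace$vif), collapse = ", "), "\n")
cat("posterior inclusion probabilities and averaged coefficients\n")
cat("(annual PU count, gaussian errors):\n")
print(ann$posterior)
write.csv(ann$posterior$terms, "results/bma_n_pus.csv", row.names = FALSE)

pu_flow <- bma_pu_flow(irsc, covariates, n_solutions = 100,
                       min_years_present = 5)
write.csv(pu_flow, "results/bma_pu_flow.csv", row.names = FALSE)
strong <- pu_flow[pu_flow$pp_flow >= 0.6, ]
cat(sprintf("\n%d of %d modelled PUs have flow pp >= 0.6 (%d positive, %d negative)\n",
            nrow(strong), nrow(pu_flow), sum(strong$beta_flow > 0),
            sum(strong$beta_flow < 0)))
cat(sprintf("mean per-PU pseudo-R2: %.2f +/- %.2f sd\n",
            mean(pu_flow$pseudo_r2), sd(pu_flow$pseudo_r2)))
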