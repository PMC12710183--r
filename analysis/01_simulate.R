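#!/usr/bin/env Rscript
# Step 1 — synthetic study generation.
#
# Builds the simulated counterpart of the stopped-flow campaign: seven
# electrophiles of known electrophilicity E, ground-truth nucleophile
# parameters N = 9.37 and s_N = 1.18, traces at pH 1 and 2 over the
# working concentration range (1.0e-3 to 2.8e-2 mol L^-1 nucleophile,
# 5e-5 mol L^-1 electrophile, 0.002 AU Gaussian noise).  The raw traces
# go to scratch/ (they are bulky and regenerable); the ground-truth
# manifest summary goes to results/.

library(diazokin)

seed <- 1202L
truth <- list(N_true = 9.37, sN_true = 1.18,
              E = c(E1 = -8.4, E2 = -7.7, E3 = -7.2, E4 = -6.7,
                    E5 = -5.7, E6 = -5.5, E7 = -5.1),
              pKa = 3.38)

camp <- generate_campaign(truth, design = experiment_design(), seed = seed)
print(camp)

dir.create("scratch", showWarnings = FALSE)
write_campaign(camp, "scratch/campaign")

dir.create("results", showWarnings = FALSE)
m <- camp$manifest
write_rate_table(
  data.frame(label = m$labels, E = m$E, k1_true = unname(m$k1_true)),
  "results/01_ground_truth.csv")

cat("Wrote", length(camp$traces), "traces to scratch/campaign and the",
    "ground-truth table to results/01_ground_truth.csv\n")
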