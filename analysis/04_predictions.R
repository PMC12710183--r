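#!/usr/bin/env Rscript
# Step 4 — predictive model and validation.
#
# Fits the N vs sigma-plus line over the three measured aminothiophenes,
# predicts N for the unmeasured 3-substituted thiophenes, converts those
# into rate constants toward 4,6-dinitrobenzotriazole (E = -9.56,
# s_N = 1), and compares with the measured rates.  Predictions within
# one to two orders of magnitude of experiment count as inside the
# conventional confidence window of reactivity-scale extrapolation.

library(diazokin)

tab2 <- load_table2()
amino <- !is.na(tab2$sigma_plus_C3)
model <- fit_sigma_plus_model(tab2$N_exp[amino], tab2$sigma_plus_C3[amino])
print(model)

tab3 <- load_table3()
pred <- data.frame(
  nucleophile = tab3$nucleophile_name,
  sigma_plus = tab3$sigma_plus,
  N_pred = predict_N(model, tab3$sigma_plus),
  E = tab3$E)
pred$k_calc <- predict_rate(tab3$N_pred, s_N = 1, E = tab3$E)
pred$k_exp <- tab3$k_exp
v <- validate_predictions(pred$k_exp, pred$k_calc, pred$nucleophile)
pred$ratio <- v$ratio

dir.create("results", showWarnings = FALSE)
write_rate_table(pred, "results/04_predictions.csv")

cat(sprintf("Predicted N: %s\n",
            paste(sprintf("%s = %.2f", pred$nucleophile, pred$N_pred),
                  collapse = ", ")))
cat(sprintf("Experimental/calculated rate ratios: %s (all within factor 100: %s)\n",
            paste(sprintf("%.1f", pred$ratio), collapse = ", "),
            attr(v, "within_confidence")))
cat("Wrote results/04_predictions.csv\n")
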