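# Shared synthetic-study ingredients for the tests.

# Ground truth mirroring the study layout: seven electrophiles with known E,
# generating parameters near the measured ones.
study_truth <- function(N_true = 9.37, sN_true = 1.18) {
  list(N_true = N_true, sN_true = sN_true,
       E = c(E1 = -8.4, E2 = -7.7, E3 = -7.2, E4 = -6.7,
             E5 = -5.7, E6 = -5.5, E7 = -5.1),
       pKa = 3.38)
}

# Brute-force Yukawa-Tsuno oracle: minimise SSE over an explicit
# (rho, r) grid, profiling out the intercept analytically at each node.
yt_grid_oracle <- function(log_k, sigma, sigma_plus,
                           rho_range = c(0, 5), r_range = c(-1, 3),
                           n_grid = 200) {
  best <- Inf
  for (rho in seq(rho_range[1], rho_range[2], length.out = n_grid)) {
    for (r in seq(r_range[1], r_range[2], length.out = n_grid)) {
      sigma_eff <- sigma + r * (sigma_plus - sigma)
      resid <- log_k - rho * sigma_eff
      sse <- sum((resid - mean(resid))^2)
      if (sse < best) best <- sse
    }
  }
  best
}
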