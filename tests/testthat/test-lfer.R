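# Linear free-energy analyses and the predictive model.

test_that("pH-averaged log rates match direct arithmetic", {
  expect_equal(average_log_rate(465, 427), (log10(427) + log10(465)) / 2)
  expect_equal(round(average_log_rate(465, 427), 3), 2.649)
  expect_equal(round(average_log_rate(14.5, 13.3), 3), 1.143)
  # single-pH record falls back to that value; empty record errors
  expect_equal(average_log_rate(100, NA), 2)
  expect_error(average_log_rate(NA_real_, NA_real_), "no k1")
})

test_that("Hammett fit recovers constructed lines and printed constants", {
  sig <- c(-0.3, -0.1, 0, 0.2, 0.5)
  ident <- hammett_fit(sig, sig, "sigma")
  expect_equal(ident$rho, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)
  expect_equal(ident$r2, 1)

  tab <- load_table1()
  log_k1 <- average_log_rate(tab$k1_pH1, tab$k1_pH2)
  hp <- hammett_fit(log_k1, tab$sigma_p_plus, "sigma_plus")
  expect_equal(hp$rho, 2.48, tolerance = 2e-3)
  expect_equal(hp$intercept, 2.91, tolerance = 2e-3)
  # enhanced-resonance scale correlates better than the plain scale
  hs <- hammett_fit(log_k1, tab$sigma_p, "sigma")
  expect_gt(hp$r2, hs$r2)

  expect_error(hammett_fit(1:2, 1:2), "at least 3")
  expect_error(hammett_fit(1:4, 1:3), "length")
})

test_that("Yukawa-Tsuno estimators recover generating parameters exactly", {
  sigma <- c(-0.27, -0.17, 0, 0.06, 0.23, 0.54, 0.66, 0.78)
  sigma_plus <- c(-0.78, -0.31, 0, -0.07, 0.11, 0.61, 0.66, 0.79)
  log_k <- 3.0 + 2.0 * (sigma + 1.5 * (sigma_plus - sigma))

  joint <- yukawa_tsuno_fit(log_k, sigma, sigma_plus, "joint-bilinear")
  expect_equal(joint$rho, 2.0, tolerance = 1e-9)
  expect_equal(joint$r, 1.5, tolerance = 1e-9)
  expect_equal(joint$intercept, 3.0, tolerance = 1e-9)

  grid <- yukawa_tsuno_fit(log_k, sigma, sigma_plus, "grid-conditional")
  expect_equal(grid$r, 1.5, tolerance = 1e-8)  # 1.50 lies on the 0.01 grid
  expect_equal(grid$rho, 2.0, tolerance = 1e-6)
  expect_gte(grid$sse + 1e-12, joint$sse)
})

test_that("Yukawa-Tsuno limits coincide with single-scale Hammett fits", {
  set.seed(5)
  sigma <- c(-0.3, -0.1, 0.05, 0.3, 0.6)
  sigma_plus <- sigma + c(-0.5, -0.15, 0, 0.02, 0.05)
  for (r_true in c(0, 1)) {
    log_k <- 1.2 + 2.5 * (sigma + r_true * (sigma_plus - sigma)) +
      rnorm(5, 0, 0.02)
    yt <- yukawa_tsuno_fit(log_k, sigma, sigma_plus, "grid-conditional")
    scale_vals <- if (r_true == 0) sigma else sigma_plus
    h <- hammett_fit(log_k, scale_vals,
                     if (r_true == 0) "sigma" else "sigma_plus")
    # conditional fit at the generating r equals the single-scale OLS, and
    # the grid optimum cannot do worse
    expect_lte(yt$sse, sum(h$residuals^2) + 1e-12)
  }
})

test_that("Yukawa-Tsuno degenerate design is handled per estimator", {
  sigma <- c(-0.3, 0, 0.2, 0.5)
  log_k <- 1 + 2 * sigma
  expect_error(yukawa_tsuno_fit(log_k, sigma, sigma, "joint-bilinear"),
               "identically zero")
  grid <- yukawa_tsuno_fit(log_k, sigma, sigma, "grid-conditional")
  expect_false(grid$r_identifiable)
  expect_true(is.na(grid$r))
  expect_equal(grid$rho, 2, tolerance = 1e-9)
})

test_that("joint Yukawa-Tsuno fit attains the brute-force SSE optimum", {
  tab <- load_table1()
  log_k1 <- average_log_rate(tab$k1_pH1, tab$k1_pH2)
  joint <- yukawa_tsuno_fit(log_k1, tab$sigma_p, tab$sigma_p_plus,
                            "joint-bilinear")
  oracle <- yt_grid_oracle(log_k1, tab$sigma_p, tab$sigma_p_plus)
  expect_lte(joint$sse, oracle + 1e-10)
})

test_that("Mayr-Patz fit inverts the generating relation", {
  E <- c(-8.4, -7.7, -7.2, -6.7, -5.7, -5.5, -5.1)
  exact <- mayr_fit(1.0 * (E + 8.0), E)
  expect_equal(exact$s_N, 1)
  expect_equal(exact$N, 8)
  expect_equal(exact$r2, 1)

  # exact inverse over a parameter grid
  for (N in c(5, 8.5, 12)) {
    for (sN in c(0.8, 1.05, 1.3)) {
      fit <- mayr_fit(sN * (E + N), E)
      expect_equal(fit$s_N, sN, tolerance = 1e-9)
      expect_equal(fit$N, N, tolerance = 1e-9)
    }
  }

  expect_error(mayr_fit(-1.0 * (E + 8.0), E), "inverted")
})

test_that("single-rate N estimation matches the reference panel", {
  expect_equal(round(n_from_single_rate(3.37e4, -5.06), 2), 9.59)
  expect_equal(n_from_single_rate(1.00e2, -5.06), 7.06, tolerance = 1e-6)
  expect_equal(n_from_single_rate(1, 0), 0)
  t2 <- load_table2()
  expect_equal(round(n_from_single_rate(t2$k_ref, t2$E_ref), 2), t2$N)
})

test_that("rate prediction and single-rate estimation are inverse", {
  for (N in c(0, 6.72, 9.37)) {
    for (E in c(-9.56, -5.06, 0)) {
      expect_equal(n_from_single_rate(predict_rate(N, 1, E), E), N,
                   tolerance = 1e-12)
    }
  }
  expect_equal(predict_rate(8.29, 1, -9.56), 5.37e-2, tolerance = 1e-3)
  expect_equal(predict_rate(0, 1, 0), 1)
})

test_that("sigma-plus model reproduces the printed line and predictions", {
  model <- fit_sigma_plus_model(N = c(9.37, 10.47, 10.02),
                                sigma_plus = c(-1.30, -1.81, -1.70))
  expect_equal(model$slope, -2.01, tolerance = 3e-3)
  expect_equal(model$intercept, 6.72, tolerance = 1e-3)
  expect_equal(predict_N(model, -0.78), 8.29, tolerance = 1e-3)
  expect_equal(predict_N(model, -0.31), 7.34, tolerance = 2e-3)
  expect_equal(predict_N(model, 0), 6.72, tolerance = 1e-3)

  ident <- fit_sigma_plus_model(c(-1, 0, 1), c(-1, 0, 1))
  expect_equal(ident$slope, 1)
  expect_equal(ident$intercept, 0, tolerance = 1e-12)

  # coincident predictors are fine as long as the design has rank 2
  ok <- fit_sigma_plus_model(c(1, 2, 3), c(0, 0, 1))
  expect_true(is.finite(ok$slope))
  expect_error(fit_sigma_plus_model(c(1, 2, 3), c(0.5, 0.5, 0.5)),
               "rank deficient")
})

test_that("prediction validation flags the confidence window", {
  v <- validate_predictions(c(4.51e-1, 9.38e-2), c(5.37e-2, 6.03e-3),
                            names = c("methoxy", "methyl"))
  expect_equal(round(v$ratio, 1), c(8.4, 15.6))
  expect_true(attr(v, "within_confidence"))

  same <- validate_predictions(2, 2)
  expect_equal(same$ratio, 1)
  # reciprocal deviations count too
  far <- validate_predictions(1e-3, 1)
  expect_false(attr(far, "within_confidence"))
  expect_error(validate_predictions(-1, 1), "positive")
})

test_that("averaged log k1 increases with substituent electron withdrawal", {
  tab <- load_table1()
  log_k1 <- average_log_rate(tab$k1_pH1, tab$k1_pH2)
  # strictly monotone in sigma_p and in E; the sigma-plus ordering is broken
  # only by the near-degenerate F/H pair (-0.07 vs 0)
  expect_true(all(diff(log_k1[order(tab$sigma_p)]) > 0))
  has_E <- !is.na(tab$E)
  expect_true(all(diff(log_k1[has_E][order(tab$E[has_E])]) > 0))
  sp_order <- order(tab$sigma_p_plus)
  violations <- sum(diff(log_k1[sp_order]) < 0)
  expect_lte(violations, 1)
})
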