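# Mechanistic simulator: speciation, steady-state rate law, ODE
# integration and trace generation.

test_that("free-base fraction follows Henderson-Hasselbalch", {
  expect_equal(free_base_fraction(3.38, 3.38), 0.5)
  # oracle: Table-derived ratio k1/k at pH 2 is 1/f
  expect_equal(free_base_fraction(2, 3.38), 0.04002, tolerance = 1e-4)
  expect_gt(free_base_fraction(12, 3.38), 0.99999)
  expect_lt(free_base_fraction(0, 3.38), 0.001)
})

test_that("steady-state kobsd obeys the QSSA rate law and its limits", {
  # irreversible intermediate: exact bimolecular limit
  p <- mechanism_params(k1 = 465, k_minus1 = 0, k2 = 100)
  expect_equal(steady_state_kobsd(p, 1e-2, pH = 1),
               465 * free_base_fraction(1, 3.38) * 1e-2)

  # re-aromatization-dominated regime reproduces the measured apparent rate
  p <- mechanism_params(k1 = 465, k_minus1 = 1e-3, k2 = 1e3)
  expect_equal(steady_state_kobsd(p, 1e-2, pH = 1), 1.93e-2,
               tolerance = 5e-3)

  # equal partitioning halves the rate
  p_half <- mechanism_params(k1 = 465, k_minus1 = 50, k2 = 50)
  p_full <- mechanism_params(k1 = 465, k_minus1 = 0, k2 = 50)
  expect_equal(steady_state_kobsd(p_half, 1e-2, 1),
               steady_state_kobsd(p_full, 1e-2, 1) / 2)

  expect_error(steady_state_kobsd(p_half, -1e-3, 1), "positive")
})

test_that("full rate law reduces to the simplified one when k2 >> k-1", {
  for (ratio in c(1e3, 1e4, 1e6)) {
    p <- mechanism_params(k1 = 100, k_minus1 = 1, k2 = ratio)
    simplified <- p$k1 * free_base_fraction(2, p$pKa) * 5e-3
    expect_equal(steady_state_kobsd(p, 5e-3, 2), simplified,
                 tolerance = 1e-3)
  }
})

test_that("ODE integration conserves mass and matches the QSSA exponential", {
  p <- mechanism_params(k1 = 465, k_minus1 = 200, k2 = 2000)
  kobsd <- steady_state_kobsd(p, 1e-2, pH = 1)
  expect_gt((p$k_minus1 + p$k2) / kobsd, 100)  # QSSA validity regime
  sol <- simulate_mechanism_ode(p, conc = 1e-2, pH = 1)

  mass <- sol$E + sol$I + sol$P
  expect_lt(max(abs(mass - 5e-5)), 1e-9)

  # electrophile decay is single-exponential at the steady-state rate
  fit <- lm(log(E) ~ time, data = sol[sol$E > 1e-9, ])
  expect_equal(-unname(coef(fit)[2]), kobsd, tolerance = 0.01)

  # closed product channel accumulates nothing
  p0 <- mechanism_params(k1 = 465, k_minus1 = 200, k2 = 1e-12)
  sol0 <- simulate_mechanism_ode(p0, 1e-2, 1,
                                 times = seq(0, 10, length.out = 50))
  expect_lt(max(sol0$P), 1e-12)
})

test_that("generated traces follow the exponential trace model", {
  tr <- generate_trace(kobsd = 5, noise_sd = 0)
  expected <- tr$A_inf - (tr$A_inf - tr$A0) * exp(-5 * tr$times)
  expect_equal(tr$absorbances, expected)

  # log-linear form has slope -kobsd
  fit <- lm(log(tr$A_inf - tr$absorbances[-200]) ~ tr$times[-200])
  expect_equal(unname(coef(fit)[2]), -5, tolerance = 1e-10)

  # half-life: halfway between endpoints at t = ln 2 / kobsd
  tr2 <- generate_trace(5, time_grid = c(0, log(2) / 5, 1), noise_sd = 0)
  expect_equal(tr2$absorbances[2], (tr2$A0 + tr2$A_inf) / 2)

  # determinism and degenerate amplitude
  a <- generate_trace(2, noise_sd = 0.002, seed = 7)
  b <- generate_trace(2, noise_sd = 0.002, seed = 7)
  expect_identical(a$absorbances, b$absorbances)
  expect_error(generate_trace(2, A0 = 0.4, A_inf = 0.4), "degenerate")
})

test_that("campaign ground truth follows the reactivity relation", {
  truth <- study_truth()
  camp <- generate_campaign(truth, seed = 3)
  # direct evaluation of the generating relation
  expect_equal(unname(camp$manifest$k1_true["E3"]),
               10^(1.18 * (-7.2 + 9.37)))
  expect_equal(unname(camp$manifest$k1_true["E3"]), 3.63e2,
               tolerance = 2e-3)
  expect_equal(length(camp$traces), 7 * 2 * 7)

  # every trace's generating kobsd is k1 * f(pH) * conc
  tr <- camp$traces[[15]]
  k1 <- camp$manifest$k1_true[[tr$label]]
  expect_equal(tr$true_kobsd,
               k1 * free_base_fraction(tr$pH, truth$pKa) *
                 tr$nucleophile_total_conc)

  # same campaign seed reproduces identical data
  camp2 <- generate_campaign(truth, seed = 3)
  expect_identical(camp$traces[[40]]$absorbances,
                   camp2$traces[[40]]$absorbances)
})

test_that("design enforces the pseudo-first-order regime", {
  expect_error(experiment_design(nucleophile_total_concs = c(1e-4, 1e-3)),
               "pseudo-first-order")
  d <- experiment_design()
  expect_true(all(d$nucleophile_total_concs >= 20 * d$electrophile_conc))
})
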