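test_that("forward model matches hand-evaluated binding arithmetic", {
  # half-occupancy at pH = pKa
  sp1 <- ligand_spectrum(6, 0.10, S = 0)
  expect_equal(forward_model(sp1, 6), 0.05)
  # fully protonated limit at pH << pKa
  expect_lt(forward_model(sp1, 2), 1e-5)
  # two sites plus intercept, hand evaluation at pH 6.5
  sp2 <- ligand_spectrum(c(5, 8), c(0.2, 0.4), S = 0.01)
  h <- 10^(-6.5)
  byhand <- 0.01 + 0.2 * 1e-5 / (1e-5 + h) + 0.4 * 1e-8 / (1e-8 + h)
  expect_equal(forward_model(sp2, 6.5), byhand)
  expect_equal(byhand, 0.2161307, tolerance = 1e-6)
})

test_that("forward model is non-decreasing in pH for non-negative ligands", {
  set.seed(31)
  for (k in 1:20) {
    ns <- sample(1:6, 1)
    sp <- ligand_spectrum(sort(runif(ns, 3, 11)), runif(ns, 0, 1e-3),
                          S = runif(1, -1e-4, 1e-4))
    q <- forward_model(sp, seq(2, 12, by = 0.1))
    expect_true(all(diff(q) >= -1e-15))
  }
})

test_that("resampling interpolates inside the span and never extrapolates", {
  g <- pka_grid()
  ser <- charge_excess_series(c(5.9, 6.1), c(1.0, 2.0))
  rs <- resample_to_fit_grid(ser, g)
  expect_equal(rs$Q[rs$pH == 6.0], 1.5)          # linear midpoint
  expect_true(all(rs$pH >= 5.9 & rs$pH <= 6.1))  # outside span omitted

  # input already on the grid passes through unchanged
  on_grid <- charge_excess_series(as.numeric(g), sin(as.numeric(g)))
  rs2 <- resample_to_fit_grid(on_grid, g)
  expect_equal(rs2$pH, as.numeric(g))
  expect_equal(rs2$Q, sin(as.numeric(g)))

  # duplicate pH readings are averaged before interpolation
  dup <- charge_excess_series(c(6, 6, 6.2), c(1, 3, 4))
  expect_equal(resample_to_fit_grid(dup, g)$Q[1], 2)

  expect_error(resample_to_fit_grid(charge_excess_series(6, 1), g),
               "fewer than 2")
})

test_that("noise-free on-grid mixtures are recovered exactly by the LPM fit", {
  g <- pka_grid()
  truth <- ligand_spectrum(c(5.0, 8.4), c(0.2e-3, 0.4e-3), S = 0.01e-3)
  ser <- charge_excess_series(as.numeric(g),
                              forward_model(truth, as.numeric(g)))
  fit <- fit_lpm(ser, g)
  expect_equal(fit$diagnostics$solver_status, "optimal")
  expect_lt(fit$diagnostics$objective_value, 1e-9)
  expect_equal(fit$spectrum$S, truth$S, tolerance = 1e-6)
  got <- fit$spectrum$sites
  expect_equal(got$L_T[abs(got$pKa - 5.0) < 1e-9], 0.2e-3, tolerance = 1e-6)
  expect_equal(got$L_T[abs(got$pKa - 8.4) < 1e-9], 0.4e-3, tolerance = 1e-6)
  expect_equal(sum(got$L_T), truth$total_LT, tolerance = 1e-9)
})

test_that("an identically zero series fits to the empty spectrum", {
  g <- pka_grid()
  ser <- charge_excess_series(as.numeric(g), rep(0, length(g)))
  fit <- fit_lpm(ser, g)
  expect_equal(fit$spectrum$sites$L_T, rep(0, length(g)))
  expect_equal(fit$spectrum$S, 0)
  expect_equal(fit$diagnostics$objective_value, 0)
})

test_that("fitted L_Ti and S scale linearly with Q", {
  set.seed(33)
  g <- pka_grid()
  truth <- ligand_spectrum(c(4.8, 7.2), c(1e-4, 3e-4), S = -2e-5)
  Q <- forward_model(truth, as.numeric(g)) + rnorm(length(g), 0, 5e-6)
  f1 <- fit_lpm(charge_excess_series(as.numeric(g), Q), g,
                report_threshold = 0)
  f2 <- fit_lpm(charge_excess_series(as.numeric(g), 2.5 * Q), g,
                report_threshold = 0)
  expect_equal(f2$spectrum$sites$L_T, 2.5 * f1$spectrum$sites$L_T,
               tolerance = 1e-6)
  expect_equal(f2$spectrum$S, 2.5 * f1$spectrum$S, tolerance = 1e-6)
})

test_that("raw-point fitting works as an alternative to the resampled grid", {
  set.seed(34)
  g <- pka_grid()
  truth <- ligand_spectrum(c(5.2, 8.0), c(2e-4, 3e-4), S = 1e-5)
  pH <- sort(runif(60, 4.05, 9.95))
  ser <- charge_excess_series(pH, forward_model(truth, pH))
  fit <- fit_lpm(ser, g, resample = FALSE)
  expect_equal(fit$diagnostics$n_points, 60)
  tot <- bin_functional_groups(fit$spectrum)
  expect_equal(unname(tot[c("carboxyl", "amine")]), c(2e-4, 3e-4),
               tolerance = 1e-8)
  expect_equal(fit$spectrum$S, 1e-5, tolerance = 1e-8)
})
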