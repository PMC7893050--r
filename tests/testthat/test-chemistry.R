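test_that("proton and hydroxide concentrations follow the activity model", {
  cfg <- default_config()
  expect_equal(proton_concentration(7, cfg), 1e-7)
  expect_equal(proton_concentration(4, cfg), 1e-4)
  expect_equal(hydroxide_concentration(7, cfg), 1e-7)
  expect_equal(hydroxide_concentration(9, cfg), 1e-5)

  # pKw other than 14: [OH-] = 10^-13.8 / 10^-9
  cfg138 <- vessel_config(eps_mass = 0.05, pKw = 13.8)
  expect_equal(hydroxide_concentration(9, cfg138), 10^(-13.8) / 10^(-9))

  # Davies correction at I = 0.01: gamma = 10^(-0.509 (0.1/1.1 - 0.003))
  cfgd <- vessel_config(eps_mass = 0.05, activity_model = "davies")
  gamma <- 10^(-0.509 * (sqrt(0.01) / (1 + sqrt(0.01)) - 0.3 * 0.01))
  expect_equal(davies_gamma(0.01), gamma)
  expect_equal(proton_concentration(7, cfgd), 1e-7 / gamma)
  expect_equal(proton_concentration(7, cfgd), 1.108e-7, tolerance = 1e-3)

  expect_error(proton_concentration(-1, cfg), "pH")
  expect_error(proton_concentration(14.5, cfg), "pH")
})

test_that("titrant concentrations are dilution-corrected by total volume", {
  cfg <- default_config()
  tc0 <- titrant_concentrations(0, 0, cfg)
  expect_equal(tc0$Ca, 0)
  expect_equal(tc0$Cb, 0)

  # hand arithmetic: 5e-5 L of 0.1 M HCl into 5 mL
  tca <- titrant_concentrations(5e-5, 0, cfg)
  expect_equal(tca$Ca, 0.1 * 5e-5 / 5.05e-3)
  # 1e-4 L of 0.01 M NaOH into 5 mL
  tcb <- titrant_concentrations(0, 1e-4, cfg)
  expect_equal(tcb$Cb, 0.01 * 1e-4 / 5.1e-3)
  expect_equal(tcb$Cb, 1.9608e-4, tolerance = 1e-4)

  expect_error(titrant_concentrations(-1e-6, 0, cfg), "non-negative")
})

test_that("charge excess matches the hand-computed balance and contract", {
  cfg <- default_config()
  # blank-like neutral point plus two real points
  pts <- data.frame(acid_volume_L = 0,
                    base_volume_L = c(1e-6, 1e-4, 2e-4),
                    pH = c(7.0, 9.0, 9.6))
  cv <- titration_curve("s", "1", "forward", cfg, pts)
  ser <- charge_excess(cv)
  expect_s3_class(ser, "charge_excess_series")
  expect_equal(nrow(ser), nrow(pts))
  expect_true(all(is.finite(ser$Q)))

  # hand oracle at the second point: (Cb + H - OH) * V / m
  Q2 <- (0.01 * 1e-4 / 5.1e-3 + 1e-9 - 1e-5) * 5.1e-3 / 0.05
  expect_equal(ser$Q[2], Q2)
  expect_equal(ser$Q[2], 1.898e-5, tolerance = 1e-3)
})

test_that("charge excess of a simulated blank closes to zero", {
  blank <- ligand_spectrum(numeric(0), numeric(0), S = 0)
  ser <- noiseless_series(blank, seed = 5)
  expect_lt(max(abs(ser$Q)), 1e-12)
})

test_that("charge excess is linear in the titrant term at fixed pH", {
  cfg1 <- default_config()
  cfg2 <- vessel_config(eps_mass = 0.05, acid_titrant_conc = 0.2,
                        base_titrant_conc = 0.02)
  pH <- c(5, 7, 9)
  pts <- data.frame(acid_volume_L = 1e-5, base_volume_L = c(2e-5, 6e-5, 9e-5),
                    pH = pH)
  q1 <- charge_excess(titration_curve("s", "1", "forward", cfg1, pts))
  q2 <- charge_excess(titration_curve("s", "1", "forward", cfg2, pts))
  # doubling both titrant concentrations doubles the (Cb - Ca) V / m part
  w <- (proton_concentration(pH, cfg1) - hydroxide_concentration(pH, cfg1)) *
    (cfg1$initial_volume + pts$acid_volume_L + pts$base_volume_L) /
    cfg1$eps_mass
  expect_equal(q2$Q - w, 2 * (q1$Q - w))
})

test_that("Q magnitudes for plausible EPS loads stay in the expected band", {
  ser <- noiseless_series(three_site_truth())
  expect_lt(max(abs(ser$Q)) * 1e3, 5)    # mMol/g
  expect_gt(max(abs(ser$Q)) * 1e3, 0)
})

test_that("curve and config invariants are enforced", {
  cfg <- default_config()
  expect_error(vessel_config(eps_mass = 0), "eps_mass")
  expect_error(vessel_config(eps_mass = 0.05, pKw = 12), "pKw")
  good <- data.frame(acid_volume_L = 0, base_volume_L = c(1e-5, 2e-5, 3e-5),
                     pH = c(5, 6, 7))
  expect_s3_class(titration_curve("s", "1", "forward", cfg, good),
                  "titration_curve")
  # both titrants varying
  bad1 <- good; bad1$acid_volume_L <- c(1e-6, 2e-6, 3e-6)
  expect_error(titration_curve("s", "1", "forward", cfg, bad1), "exactly one")
  # non-increasing dispensed volume
  bad2 <- good; bad2$base_volume_L <- c(1e-5, 3e-5, 2e-5)
  expect_error(titration_curve("s", "1", "forward", cfg, bad2),
               "strictly increasing")
  expect_error(titration_curve("s", "1", "forward", cfg, good[1:2, ]),
               "at least 3")
})
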