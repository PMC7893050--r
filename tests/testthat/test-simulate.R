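test_that("equilibrium pH solves classic closed-form cases", {
  cfg <- default_config()
  blank <- ligand_spectrum(numeric(0), numeric(0), S = 0)
  # strong acid limit: Ca = 1e-4 M of strong acid gives pH 4.0
  expect_equal(solve_equilibrium_pH(blank, 1e-4, 0, cfg), 4.0,
               tolerance = 1e-4)
  # neutral water
  expect_equal(solve_equilibrium_pH(blank, 0, 0, cfg), 7.0, tolerance = 1e-6)
  # half-equivalence of a single pKa-6 site dominating the water terms:
  # l = 0.01 M in the vessel, Cb - Ca = l/2 -> pH = pKa
  hh <- ligand_spectrum(6, 1e-3, S = 0)
  expect_equal(solve_equilibrium_pH(hh, 0, 5e-3, cfg), 6.0, tolerance = 5e-4)
})

test_that("every noiseless simulated point closes the charge balance", {
  spec <- noiseless_spec()
  cv <- simulate_titration(spec)
  cfg <- spec$config
  for (curve in cv) {
    tc <- titrant_concentrations(curve$points$acid_volume_L,
                                 curve$points$base_volume_L, cfg)
    h <- proton_concentration(curve$points$pH, cfg)
    oh <- hydroxide_concentration(curve$points$pH, cfg)
    l <- outer(h, 10^(-spec$truth$sites$pKa),
               function(hh, kk) kk / (kk + hh)) %*% spec$truth$sites$L_T
    f <- (tc$Cb - tc$Ca + h - oh) -
      (as.vector(l) + spec$truth$S) * cfg$eps_mass / tc$V_total
    expect_lt(max(abs(f)), 1e-12)
  }
})

test_that("noiseless simulation reproduces the forward model exactly", {
  spec <- noiseless_spec()
  ser <- charge_excess(simulate_titration(spec)$rep1_forward)
  pred <- forward_model(spec$truth, ser$pH)
  expect_lt(max(abs(ser$Q - pred)), 1e-10)
})

test_that("noiseless pH is monotone in dispensed titrant volume", {
  cv <- simulate_titration(noiseless_spec())
  expect_true(all(diff(cv$rep1_forward$points$pH) > 0))   # base direction up
  expect_true(all(diff(cv$rep1_reverse$points$pH) < 0))   # acid direction down
})

test_that("zero noise gives identical replicates; fixed seed gives identical output", {
  spec <- noiseless_spec(n_replicates = 3)
  cv <- simulate_titration(spec)
  expect_length(cv, 6)                       # forward + reverse per replicate
  expect_identical(cv$rep1_forward$points, cv$rep2_forward$points)
  expect_identical(cv$rep1_forward$points, cv$rep3_forward$points)

  noisy <- synthetic_spec(three_site_truth(), config = default_config(),
                          n_replicates = 2, seed = 99)
  a <- simulate_titration(noisy)
  b <- simulate_titration(noisy)
  expect_identical(a, b)
  # replicates have distinct noise streams
  expect_false(identical(a$rep1_forward$points$pH, a$rep2_forward$points$pH))
})

test_that("the simulator leaves the caller's RNG state untouched", {
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_titration(noiseless_spec()))
  expect_identical(.Random.seed, before)
})

test_that("fixed-volume dosing mode also closes and titrates through the grid", {
  sch <- titration_schedule(mode = "fixed", n_steps = 40, base_step = 3e-4,
                            acid_step = 3e-5, acid_predose = 3e-5)
  spec <- synthetic_spec(three_site_truth(), config = default_config(),
                         schedule = sch, noise = list(pH_sd = 0, volume_sd = 0),
                         n_replicates = 1, seed = 4)
  cv <- simulate_titration(spec)
  fw <- cv$rep1_forward
  expect_equal(nrow(fw$points), 40)
  expect_true(all(diff(fw$points$pH) > 0))
  expect_gt(max(fw$points$pH), 10)
  ser <- charge_excess(fw)
  expect_lt(max(abs(ser$Q - forward_model(spec$truth, ser$pH))), 1e-10)
})

test_that("presets carry the documented ground truths", {
  ps <- preset_specs()
  expect_named(ps, c("minimal", "march-like", "october-like"))
  expect_equal(nrow(ps$minimal$truth$sites), 1)
  expect_equal(ps$minimal$noise$pH_sd, 0)
  oct_carb <- bin_functional_groups(ps[["october-like"]]$truth)[["carboxyl"]]
  expect_equal(oct_carb * 1e3, 0.461)          # mMol/g, carboxyl-rich
  mar_carb <- bin_functional_groups(ps[["march-like"]]$truth)[["carboxyl"]]
  expect_lt(mar_carb, oct_carb)                # carboxyl-poor vs -rich
  # each preset survives the simulate -> fit -> bin round trip
  for (nm in names(ps)) {
    sp <- ps[[nm]]
    sp$noise <- list(pH_sd = 0, volume_sd = 0)
    sp$n_replicates <- 1
    fit <- fit_lpm(charge_excess(simulate_titration(sp)$rep1_forward))
    got <- bin_functional_groups(fit$spectrum)
    want <- bin_functional_groups(sp$truth)
    expect_equal(got, want, tolerance = 1e-6)
  }
})
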