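# Shared fixtures: small configurations and simulated experiments used
# across test files. Everything is generated in code; no stored data.

default_config <- function(...) vessel_config(eps_mass = 0.05, ...)

# a mid-weight three-site truth covering three functional-group classes
three_site_truth <- function() {
  ligand_spectrum(c(4.6, 6.8, 8.4), c(2.5e-4, 2.6e-4, 7.2e-4), S = 1e-5)
}

noiseless_spec <- function(truth = three_site_truth(), seed = 3,
                           n_replicates = 1, ...) {
  synthetic_spec(truth, config = default_config(),
                 noise = list(pH_sd = 0, volume_sd = 0),
                 n_replicates = n_replicates, seed = seed, ...)
}

# simulate one noiseless forward run and return its charge-excess series
noiseless_series <- function(truth = three_site_truth(), seed = 3) {
  charge_excess(simulate_titration(noiseless_spec(truth, seed))$rep1_forward)
}

# random on-grid spectrum for recovery tests (units mol/g)
random_on_grid_truth <- function(grid = pka_grid()) {
  ns <- sample(1:5, 1)
  pk <- sort(sample(as.numeric(grid), ns))
  ligand_spectrum(pk, stats::runif(ns, 0.01e-3, 0.5e-3),
                  S = stats::runif(1, -0.05e-3, 0.05e-3))
}
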