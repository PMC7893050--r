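---
title: "Quantifying EPS functional groups from potentiometric titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying EPS functional groups from potentiometric titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epstitrate)
```

## The measurement and the model

A potentiometric titration of an EPS suspension records pH after each
addition of strong acid or base. The package reduces each point *j* to a
charge excess per gram of EPS,

$$Q_j = \left(C_{b,j} - C_{a,j} + [\mathrm{H}^+]_j - [\mathrm{OH}^-]_j\right)
\frac{V_j}{m},$$

and explains it with a discrete proton-binding model,

$$Q_j = \sum_{i=1}^{n} \frac{K_{a,i}\,L_{T,i}}{K_{a,i} + [\mathrm{H}^+]_j} + S,$$

i.e. a mixture of independent monoprotic ligands at fixed candidate acidity
constants plus a constant offset $S$ (the acid neutralization capacity of
the surface). Each term is a site concentration $L_{T,i}$ (mol g$^{-1}$)
times its deprotonated fraction at the ambient proton concentration, so the
model is non-decreasing in pH whenever all $L_{T,i} \ge 0$.

Assumptions: equilibrium at every point (no kinetic hysteresis), no
carbonate species (the vessel is degassed under N$_2$), monoprotic
non-interacting sites, and an inert counter-ion for the deprotonated sites
(they enter the balance only through their proton occupancy).

## Parameters that matter

* **Vessel** (`vessel_config`): initial volume 5 mL of 0.01 M KCl,
  titrants 0.1 M HCl and 0.01 M NaOH, EPS dry mass 0.020–0.080 g
  (required), pKw 14.0 at 25 °C. Titrant concentrations are
  dilution-corrected by the running total volume $V_0+V_a+V_b$ at every
  point; with a 0.1 M titrant dosed into 5 mL this correction is physically
  required, and it is applied uniformly.
* **Activity** (`activity_model`): the default treats $10^{-\mathrm{pH}}$ as
  the proton concentration. Because the original workflow for such data does
  not state whether activity corrections were applied, a Davies correction
  at the fixed electrolyte ionic strength (0.01 M) is available as an
  option rather than hard-wired; at this ionic strength the coefficient is
  $\gamma \approx 0.90$, a ~10% effect on the water terms only.
* **pKa grid** (`pka_grid`): candidate sites at pKa 4–10 every 0.2 units
  (31 sites). The same values double as the pH evaluation grid after
  resampling — one grid, both roles. Measured points outside 4–10 are
  truncated from the fit.
* **Fit** (`fit_lpm`): L1 objective (the classical linear-programming
  formulation of the inversion), $L_{T,i} \ge 0$, $S$ free in sign (blank
  handling can shift the balance either way). Sites fitted below
  `report_threshold` (default $10^{-6}$ mol g$^{-1}$) are reported as zero
  to suppress numerically idle LP vertices. By default the series is first
  linearly interpolated onto the grid pH values; `resample = FALSE` fits on
  the raw measured points instead — both are legitimate readings of the
  method and the choice is exposed.
* **Classes** (`functional_group_scheme`): carboxyl 3–5.8, phosphoryl 6–8,
  amine 8–9, hydroxyl 9–10. A class is half-open $[lo, hi)$ where its upper
  bound coincides with the next class's lower bound; where a gap follows
  (5.8–6) and at the top of the last class the bound is included. This
  assigns the boundary grid sites deterministically (5.8 → carboxyl, 6.0 →
  phosphoryl, 8.0 → amine, 9.0 and 10.0 → hydroxyl). The carboxyl range
  keeps 3 as its printed lower bound even though the default grid starts at
  4, so no sites below 4 can occur. The hydroxyl class is always reported
  explicitly, even when its total is zero.
* **Replicates** (`aggregate_replicates`): mean and sample standard
  deviation (n−1) over replicate class totals; a single replicate reports
  sd as NA.

## The linear program and its numerics

Minimizing $\sum_j |Q_{obs,j} - Q_{pred,j}|$ under non-negativity is cast
as a linear program with per-point slack pairs $u_j, v_j \ge 0$ and the
intercept split into $S^+ - S^-$. The slack pair of each row provides an
immediate feasible basis, so no phase-1 is needed; the solver is a dense
primal simplex maintained by product-form basis-inverse updates with
periodic refactorization.

Titration design columns at adjacent pKa values are nearly collinear, and
optimal bases are heavily degenerate (many points fitted exactly,
especially on noise-free data). The pivot rules are therefore chosen for
stability: an entering column whose transformed pivot candidates are all
numerically negligible is rejected as basis-dependent at working precision;
near-tied ratio-test rows resolve to the largest pivot magnitude; and
Bland's smallest-index rule takes over after a long degenerate stall, which
guarantees termination. Reduced-cost and pivot tolerances are $10^{-9}$ on
a problem scaled to $\max|Q| = 1$; the solver is deterministic (no random
restarts), so a fixed input yields a fixed spectrum.

Two consequences worth knowing. First, when two adjacent grid sites can
trade mass at equal objective, the solver lands on one vertex of the
optimal face and no canonical vertex is enforced — all downstream reporting
uses class sums, which are invariant to such trades. Second, the reported
`objective_value` is the LP optimum before the reporting threshold is
applied, while residuals and rmse describe the returned (thresholded)
spectrum.

## What the simulator emulates

`simulate_titration` generates curves by solving the equilibrium charge
balance for pH (or, equivalently, for the titrant volume). The residual
$f(\mathrm{pH})$ is strictly decreasing, so the root in (0, 14) is unique;
it is bracketed and polished by Newton steps to $|f| \le 10^{-13}$ M.

The default dosing mode emulates a dynamic-endpoint auto-titrator: the
instrument doses to target pH values (every 0.1 unit from 3.0 to 10.6, a
superset of the fit grid), and the required volume follows in closed form
because site occupancies depend on pH only. The forward run titrates base
upward from a 30 µL acid pre-dose; the reverse run starts from the forward
run's final base charge and titrates acid back down. Setpoint dosing was
chosen over fixed-volume steps (also available) because it samples forward
and reverse runs at identical pH values: their overlay then isolates
hysteresis, instead of mixing it with interpolation error between
mismatched abscissae. Unreachable targets (e.g. below the pre-dose pH, or
beyond what the 0.01 M base can drive against heavy site loads) are
skipped, never extrapolated.

The noise model is additive Gaussian on recorded pH (default sd 0.02,
typical glass-electrode repeatability) and multiplicative Gaussian on each
dispensed volume (default 0.5%); the pre-dose is treated as exact. One seed
governs everything; per-replicate and per-direction substreams are split
deterministically, so a fixed spec is byte-reproducible. Presets
(`preset_specs`) provide a minimal single-site fixture and two mixtures
whose class loads match the magnitudes reported for mat EPS
(carboxyl-poor "march-like", carboxyl-rich "october-like" with a
0.461 mmol/g carboxyl class).

What the simulator does **not** emulate: electrode drift and junction
potentials, CO$_2$ ingress, kinetic (non-equilibrium) binding, multiprotic
or electrostatically coupled sites, and off-grid "true" pKa values in the
presets. Passing recovery tests on this generator therefore demonstrates
that the inversion chain is correct and noise-robust under the stated error
model — not that any real titration is free of those artifacts.

## Validation choices and problem sizes

The package's tests and the acceptance script exercise: exact recovery of
20 random on-grid mixtures (1–5 sites, $L_{T,i}$ 0.01–0.5 mmol/g, $S$
within ±0.05 mmol/g) from noise-free simulations; LP optimality against an
exhaustive lattice search on 10 tiny instances (5 pH points, 3 sites,
lattice step 0.01); 100 noisy replicates of the carboxyl-rich preset for
the median class-total error; charge-balance closure of every simulated
point; and the QC contracts (zero rmse on identity, no hysteresis without
noise, measured-vs-modeled rmse commensurate with the injected Q-noise).
These sizes keep a full run in the tens of seconds while leaving each check
statistically meaningful.

## Known limitations

* The inversion is only as identifiable as the data span: sites outside the
  measured pH range (or outside 4–10) are invisible, and adjacent-site
  degeneracy means individual $L_{T,i}$ are less reliable than class totals.
* Fits use the forward (base-direction) run; the reverse run is a QC
  control, not additional fitting data.
* The L1 norm is robust to isolated outliers but, like any norm choice,
  shapes how noise maps into the spectrum; no uncertainty is propagated to
  the fitted $L_{T,i}$ beyond replicate scatter.
* File serialization rounds to 6 significant digits; round-tripping through
  CSV/TSV is reproducible to that precision, not to machine precision.
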