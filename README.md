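# epstitrate

Potentiometric titration analysis of microbial-mat exopolymeric substances
(EPS): from raw titrant additions and pH readings to concentrations of
carboxyl, phosphoryl, amine and hydroxyl functional groups per gram of EPS.

## Who this is for

Biogeochemists characterizing the acid–base reactivity of EPS (or other
organic/cell-surface material) by acid–base titration. The proton-active
functional groups of EPS bind cations and are candidate nucleation sites for
authigenic minerals such as dolomite, so their site densities and acidity
constants are the quantities of interest.

## The model

Each titration point *j* is reduced to a **charge excess** per gram of EPS:

```
Q_j = (Cb_j − Ca_j + [H+]_j − [OH−]_j) · V_j / m        (mol g⁻¹)
```

where `Ca_j`, `Cb_j` are the dilution-corrected concentrations of added HCl
and NaOH, `[H+] = 10^(−pH)` (optionally Davies-corrected for activity),
`[OH−] = Kw/[H+]`, `V_j` the running vessel volume and `m` the EPS dry mass.
The charge excess is explained by a discrete set of `n` monoprotic binding
sites plus a constant:

```
Q_j = Σᵢ Ka_i · L_Ti / (Ka_i + [H+]_j) + S
```

with site concentrations `L_Ti ≥ 0` on a fixed pKa grid (default 4–10 in
0.2-unit steps, `Ka_i = 10^(−pKa_i)`) and an intercept `S`, the acid
neutralization capacity of the EPS surface. The inversion is the classical
**linear programming method (LPM)**: minimize `Σ_j |Q_obs,j − Q_pred,j|`
subject to `L_Ti ≥ 0`, linearized with slack variables and solved exactly by
a deterministic simplex. Fitted sites are pooled by pKa range — carboxyl
3–5.8, phosphoryl 6–8, amine 8–9, hydroxyl 9–10 — and replicate titrations
are summarized as mean ± sd per class in mMol/g EPS.

Because raw titration data of this kind are rarely deposited, the package
also ships a charge-balance **equilibrium simulator** (`simulate_titration`)
that generates forward/reverse titration curves from a known ligand mixture,
emulating a dynamic-endpoint auto-titrator, so the whole chain can be
validated by parameter recovery.

## Worked example

Simulate a carboxyl-rich triplicate experiment with realistic electrode and
dosing noise, fit it, and summarize:

```r
library(epstitrate)

spec <- preset_specs()[["october-like"]]   # carboxyl-class truth 0.461 mMol/g
res  <- run_titration_pipeline(spec)

res$fits$rep1$spectrum
#> Ligand spectrum: 8 active site(s) of 31, total L_T = 0.001455 mol/g, S = -5.407e-06 mol/g
#>  pKa L_T_mmol_per_g
#>  4.2       0.110000
#>  4.4       0.057150
#>  5.2       0.220100
#>  ...

res$report
#>  Functional Group pKa Range october-like Average L_T (mMol/g EPS)
#>  Carboxyl         3–5.8     0.447 ± 0.038
#>  Phosphoryl       6–8       0.265 ± 0.028
#>  Amine            8–9       0.726 ± 0.004
#>  Hydroxyl         9–10      0.001 ± 0.001

res$qc$rep1_forward_vs_reverse
#> Agreement: rmse 5.395e-06, max |diff| 1.684e-05 over 31 points (pH 4.00-10.00) -> PASS
```

Reading: the LP places the ground-truth mixture (carboxyl 0.461, phosphoryl
0.260, amine 0.721 mMol/g) onto nearby grid sites; under noise some mass
spreads over adjacent pKa values, but the class totals — the reported
quantity — land within a few percent of truth, and the forward/reverse
overlay shows no hysteresis beyond the injected noise.

For measured data, write your titrator export to the documented CSV dialect
(`sample_id,replicate_id,direction,acid_volume_L,base_volume_L,pH`) and run
`read_titration_curves()` → `charge_excess()` → `fit_lpm()` →
`bin_functional_groups()` → `aggregate_replicates()`, or use the file-based
drivers (`fit_curves_file()`, `summarize_spectra_files()`; a thin CLI lives
in `inst/cli/epstitrate.R`).

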