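#' Davies activity coefficient for a singly charged ion
#'
#' log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I) with A = 0.509 at
#' 25 C. Used to convert the pH-meter activity 10^-pH into a free proton
#' concentration at the background-electrolyte ionic strength.
#'
#' @param ionic_strength Ionic strength in mol/L.
#' @param charge Ion charge (default 1).
#' @return The dimensionless activity coefficient gamma (< 1 for I > 0).
#' @export
davies_gamma <- function(ionic_strength, charge = 1) {
  stop_unless(is.numeric(ionic_strength) && all(ionic_strength >= 0),
              "ionic_strength must be non-negative")
  sI <- sqrt(ionic_strength)
  10^(-0.509 * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength))
}

#' Proton concentration at a measured pH
#'
#' Under the \code{"ideal"} activity model the free proton concentration is
#' 10^-pH. Under \code{"davies"} the electrode activity 10^-pH is divided by
#' the single-charge Davies coefficient evaluated at the electrolyte ionic
#' strength of \code{config}.
#'
#' @param pH Numeric vector of pH values in (0, 14).
#' @param config A \code{\link{vessel_config}}.
#' @return Proton concentration(s) in mol/L.
#' @examples
#' cfg <- vessel_config(eps_mass = 0.05)
#' proton_concentration(7, cfg)             # 1e-7
#' @export
proton_concentration <- function(pH, config) {
  stop_unless(is_vessel_config(config), "config must be a vessel_config")
  stop_unless(all(is.finite(pH) & pH > 0 & pH < 14), "pH must lie in (0, 14)")
  h <- 10^(-pH)
  if (config$activity_model == "davies") {
    h <- h / davies_gamma(config$electrolyte_conc)
  }
  h
}

#' Hydroxide concentration at a measured pH
#'
#' Returns Kw / [H+] with Kw = 10^-pKw and [H+] from
#' \code{\link{proton_concentration}} (so the activity model enters through
#' the proton term).
#'
#' @inheritParams proton_concentration
#' @return Hydroxide concentration(s) in mol/L.
#' @export
hydroxide_concentration <- function(pH, config) {
  10^(-config$pKw) / proton_concentration(pH, config)
}

#' Dilution-corrected titrant concentrations at a titration point
#'
#' Concentrations of the added strong acid and base in the vessel,
#' corrected for the total volume after all cumulative additions:
#' Ca = c_HCl * Va / (V0 + Va + Vb), Cb = c_NaOH * Vb / (V0 + Va + Vb).
#'
#' @param acid_volume_L,base_volume_L Cumulative titrant volumes in litres
#'   (vectors of equal length).
#' @param config A \code{\link{vessel_config}}.
#' @return A list with numeric components \code{Ca}, \code{Cb} (mol/L) and
#'   \code{V_total} (L).
#' @export
titrant_concentrations <- function(acid_volume_L, base_volume_L, config) {
  stop_unless(is_vessel_config(config), "config must be a vessel_config")
  stop_unless(all(acid_volume_L >= 0) && all(base_volume_L >= 0),
              "titrant volumes must be non-negative")
  V <- config$initial_volume + acid_volume_L + base_volume_L
  list(Ca = config$acid_titrant_conc * acid_volume_L / V,
       Cb = config$base_titrant_conc * base_volume_L / V,
       V_total = V)
}

#' Charge excess of a titration curve
#'
#' For each point j of the curve computes the net titratable charge
#' Q_j = (Cb_j - Ca_j + [H+]_j - [OH-]_j) * V_total_j / m, in mol per gram of
#' EPS, where Ca/Cb are the dilution-corrected titrant concentrations, the
#' proton and hydroxide terms follow the configured activity model, and m is
#' the EPS dry mass. The per-gram normalization makes fitted ligand
#' concentrations directly comparable to functional-group totals reported in
#' mMol/g EPS.
#'
#' Carbonate species are assumed absent (degassed, N2-purged vessel).
#'
#' @param curve A \code{\link{titration_curve}}.
#' @return A \code{\link{charge_excess_series}} with one entry per point.
#' @examples
#' cfg <- vessel_config(eps_mass = 0.05)
#' pts <- data.frame(acid_volume_L = 0,
#'                   base_volume_L = c(5e-5, 1e-4, 2e-4),
#'                   pH = c(7.5, 8.6, 9.8))
#' cv <- titration_curve("s", "1", "forward", cfg, pts)
#' charge_excess(cv)
#' @export
charge_excess <- function(curve) {
  stop_unless(is_titration_curve(curve), "curve must be a titration_curve")
  cfg <- curve$config
  stop_unless(cfg$eps_mass > 0, "eps_mass must be positive")
  p <- curve$points
  tc <- titrant_concentrations(p$acid_volume_L, p$base_volume_L, cfg)
  h <- proton_concentration(p$pH, cfg)
  oh <- hydroxide_concentration(p$pH, cfg)
  Q <- (tc$Cb - tc$Ca + h - oh) * tc$V_total / cfg$eps_mass
  charge_excess_series(p$pH, Q,
                       sample_id = curve$sample_id,
                       replicate_id = curve$replicate_id,
                       direction = curve$direction,
                       config = cfg)
}
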