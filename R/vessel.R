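#' Titration vessel configuration
#'
#' Describes the physical set-up of a potentiometric titration of an EPS
#' (exopolymeric substances) suspension: initial electrolyte volume, titrant
#' concentrations, sample dry mass and the thermodynamic constants used when
#' converting pH readings to proton/hydroxide concentrations.
#'
#' Defaults correspond to a typical auto-titrator run on purified mat EPS:
#' 5 mL of 0.01 M KCl electrolyte, 0.1 M HCl and 0.01 M NaOH titrants, and a
#' 20--80 mg sample degassed under N2 (so carbonate species are absent from
#' the charge balance).
#'
#' @param eps_mass Dry mass of EPS in the vessel, in grams. Required;
#'   typically 0.020--0.080 g.
#' @param initial_volume Initial electrolyte volume in litres (default 5e-3).
#' @param electrolyte_conc Background electrolyte (KCl) molarity, also used as
#'   the ionic strength for the Davies activity correction (default 0.01).
#' @param acid_titrant_conc Acid titrant (HCl) molarity (default 0.1).
#' @param base_titrant_conc Base titrant (NaOH) molarity (default 0.01).
#' @param temperature Temperature in degrees Celsius (default 25). Recorded
#'   for provenance; no temperature correction of pKw is applied.
#' @param pKw Negative log of the water ion product (default 14.0, 25 C).
#'   Must lie in [13, 15].
#' @param activity_model Either \code{"ideal"} (proton concentration equals
#'   10^-pH) or \code{"davies"} (the 10^-pH activity is divided by a
#'   single-charge Davies activity coefficient at the electrolyte ionic
#'   strength).
#' @return An object of class \code{vessel_config}.
#' @examples
#' cfg <- vessel_config(eps_mass = 0.05)
#' cfg$initial_volume
#' @export
vessel_config <- function(eps_mass,
                          initial_volume = 5e-3,
                          electrolyte_conc = 0.01,
                          acid_titrant_conc = 0.1,
                          base_titrant_conc = 0.01,
                          temperature = 25,
                          pKw = 14.0,
                          activity_model = c("ideal", "davies")) {
  activity_model <- match.arg(activity_model)
  stop_unless(is.numeric(eps_mass) && length(eps_mass) == 1 && is.finite(eps_mass) &&
                eps_mass > 0, "eps_mass must be a single positive number (grams)")
  for (nm in c("initial_volume", "electrolyte_conc", "acid_titrant_conc",
               "base_titrant_conc")) {
    v <- get(nm)
    stop_unless(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
                sprintf("%s must be a single positive number", nm))
  }
  stop_unless(is.numeric(pKw) && length(pKw) == 1 && pKw >= 13 && pKw <= 15,
              "pKw must lie in [13, 15]")
  structure(
    list(eps_mass = eps_mass,
         initial_volume = initial_volume,
         electrolyte_conc = electrolyte_conc,
         acid_titrant_conc = acid_titrant_conc,
         base_titrant_conc = base_titrant_conc,
         temperature = temperature,
         pKw = pKw,
         activity_model = activity_model),
    class = "vessel_config")
}

#' @export
print.vessel_config <- function(x, ...) {
  cat("Titration vessel configuration\n")
  cat(sprintf("  EPS mass:        %.4f g\n", x$eps_mass))
  cat(sprintf("  Initial volume:  %.3f mL of %.3g M KCl\n",
              x$initial_volume * 1e3, x$electrolyte_conc))
  cat(sprintf("  Titrants:        %.3g M HCl / %.3g M NaOH\n",
              x$acid_titrant_conc, x$base_titrant_conc))
  cat(sprintf("  pKw %.2f, %g C, activity model: %s\n",
              x$pKw, x$temperature, x$activity_model))
  invisible(x)
}

stop_unless <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

is_vessel_config <- function(x) inherits(x, "vessel_config")
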