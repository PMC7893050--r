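#' Candidate pKa grid for the discrete ligand spectrum
#'
#' The linear-programming inversion places one candidate monoprotic binding
#' site at every grid value; the same values serve as the default pH
#' evaluation grid after resampling. The default, pKa 4 to 10 in 0.2-unit
#' steps (31 sites), matches the range over which mat-EPS titration data are
#' informative.
#'
#' @param start,stop Grid end points (default 4 and 10), start < stop.
#' @param step Grid spacing (default 0.2); (stop - start)/step must be an
#'   integer within tolerance.
#' @return An object of class \code{pka_grid}: numeric vector of pKa values
#'   with attributes \code{start}, \code{stop}, \code{step}.
#' @examples
#' length(pka_grid())   # 31
#' @export
pka_grid <- function(start = 4.0, stop = 10.0, step = 0.2) {
  stop_unless(start < stop, "start must be below stop")
  stop_unless(step > 0, "step must be positive")
  n <- (stop - start) / step
  stop_unless(abs(n - round(n)) < 1e-8, "(stop - start)/step must be integral")
  sites <- start + step * (0:round(n))
  structure(sites, start = start, stop = stop, step = step, class = "pka_grid")
}

is_pka_grid <- function(x) inherits(x, "pka_grid")

#' Discrete ligand spectrum
#'
#' The fitted (or ground-truth) proton-binding model: concentrations L_Ti of
#' monoprotic ligands at fixed pKa values, plus a constant intercept S (the
#' acid neutralization capacity of the EPS surface).
#'
#' @param pKa Numeric vector of site pKa values.
#' @param L_T Numeric vector of site concentrations (mol per gram EPS),
#'   all >= 0, same length as \code{pKa}.
#' @param S Intercept, mol per gram EPS (may be negative).
#' @return An object of class \code{ligand_spectrum} with elements
#'   \code{sites} (data.frame \code{pKa}, \code{L_T}), \code{S} and
#'   \code{total_LT} (= sum of L_T).
#' @examples
#' sp <- ligand_spectrum(pKa = c(4.6, 8.4), L_T = c(2e-4, 7e-4), S = 1e-5)
#' sp$total_LT
#' @export
ligand_spectrum <- function(pKa, L_T, S = 0) {
  stop_unless(length(pKa) == length(L_T), "pKa and L_T must have equal length")
  stop_unless(all(is.finite(pKa)) && all(is.finite(L_T)) && is.finite(S),
              "non-finite spectrum values")
  stop_unless(all(L_T >= 0), "all ligand concentrations L_T must be >= 0")
  structure(
    list(sites = data.frame(pKa = as.numeric(pKa), L_T = as.numeric(L_T)),
         S = as.numeric(S),
         total_LT = sum(L_T)),
    class = "ligand_spectrum")
}

is_ligand_spectrum <- function(x) inherits(x, "ligand_spectrum")

#' @export
print.ligand_spectrum <- function(x, digits = 4, ...) {
  active <- x$sites[x$sites$L_T > 0, , drop = FALSE]
  cat(sprintf("Ligand spectrum: %d active site(s) of %d, total L_T = %.4g mol/g, S = %.4g mol/g\n",
              nrow(active), nrow(x$sites), x$total_LT, x$S))
  if (nrow(active)) {
    print(data.frame(pKa = active$pKa,
                     L_T_mmol_per_g = signif(active$L_T * 1e3, digits)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Predicted charge excess of a ligand spectrum
#'
#' Evaluates the binding model at given pH values:
#' Q(pH) = sum_i Ka_i L_Ti / (Ka_i + [H+]) + S, with Ka_i = 10^-pKa_i and
#' [H+] = 10^-pH (ideal) or the Davies-corrected concentration when a
#' \code{config} with \code{activity_model = "davies"} is supplied.
#'
#' With all L_Ti >= 0 the prediction is non-decreasing in pH: each site
#' contributes its deprotonated fraction times its concentration.
#'
#' @param spectrum A \code{\link{ligand_spectrum}}.
#' @param pH Numeric vector of pH values in (0, 14).
#' @param config Optional \code{\link{vessel_config}} controlling the
#'   activity model; ideal 10^-pH is used when omitted.
#' @return Numeric vector of predicted charge excess, in the units of
#'   \code{L_T} and \code{S}.
#' @examples
#' sp <- ligand_spectrum(6, 0.10, S = 0)
#' forward_model(sp, 6)   # half-occupancy: 0.05
#' @export
forward_model <- function(spectrum, pH, config = NULL) {
  stop_unless(is_ligand_spectrum(spectrum), "spectrum must be a ligand_spectrum")
  stop_unless(all(is.finite(pH) & pH > 0 & pH < 14), "pH must lie in (0, 14)")
  h <- if (is.null(config)) 10^(-pH) else proton_concentration(pH, config)
  occ <- occupancy_matrix(h, spectrum$sites$pKa)
  as.vector(occ %*% spectrum$sites$L_T) + spectrum$S
}

# deprotonated-fraction design matrix: rows = proton concentrations,
# cols = candidate sites
occupancy_matrix <- function(h, pKa) {
  Ka <- 10^(-pKa)
  outer(h, Ka, function(hh, kk) kk / (kk + hh))
}
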