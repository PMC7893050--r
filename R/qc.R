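#' Agreement between two charge-excess series
#'
#' Quality-control comparison of forward vs reverse runs or of sample
#' replicates: both series are resampled onto the shared pH grid, restricted
#' to the pH values present in both, and compared by root-mean-square and
#' maximum absolute difference of Q. In an equilibrium system a noiseless
#' forward and reverse titration of the same sample coincide (no
#' hysteresis), so the differences measure drift, hysteresis or replicate
#' scatter.
#'
#' @param a,b \code{\link{charge_excess_series}} objects with overlapping
#'   pH spans.
#' @param grid A \code{\link{pka_grid}} supplying the comparison pH values.
#' @param pass_fraction Pass threshold: the comparison passes when rmse is
#'   at most this fraction (default 0.05) of the combined observed Q range.
#' @return A list of class \code{agreement_report}: \code{rmse},
#'   \code{max_abs_diff}, \code{n_compared}, \code{overlap_pH_span},
#'   \code{pass_flag}, \code{threshold}.
#' @export
compare_series <- function(a, b, grid = pka_grid(), pass_fraction = 0.05) {
  stop_unless(is_charge_excess_series(a) && is_charge_excess_series(b),
              "a and b must be charge_excess_series")
  ra <- resample_to_fit_grid(a, grid)
  rb <- resample_to_fit_grid(b, grid)
  common <- intersect(ra$pH, rb$pH)
  if (length(common) < 1) stop("no overlapping pH span on the comparison grid",
                               call. = FALSE)
  qa <- ra$Q[match(common, ra$pH)]
  qb <- rb$Q[match(common, rb$pH)]
  d <- qa - qb
  qrange <- diff(range(c(qa, qb)))
  thr <- pass_fraction * qrange
  structure(list(rmse = sqrt(mean(d^2)),
                 max_abs_diff = max(abs(d)),
                 n_compared = length(common),
                 overlap_pH_span = range(common),
                 pass_flag = sqrt(mean(d^2)) <= thr,
                 threshold = thr),
            class = "agreement_report")
}

#' Agreement between measured and modeled charge excess
#'
#' Compares an observed charge-excess series against the predictions of a
#' fitted ligand spectrum at the same pH values (no resampling): the
#' measured-vs-modeled overlay used to judge the quality of an LPM fit.
#'
#' @param series A \code{\link{charge_excess_series}} (non-empty).
#' @param spectrum A fitted \code{\link{ligand_spectrum}}.
#' @param pass_fraction Pass threshold as a fraction (default 0.05) of the
#'   observed Q range.
#' @param config Optional \code{\link{vessel_config}} for the activity model;
#'   taken from the series attributes when available.
#' @return An \code{agreement_report}, as for \code{\link{compare_series}}.
#' @export
measured_vs_modeled <- function(series, spectrum, pass_fraction = 0.05,
                                config = NULL) {
  stop_unless(is_charge_excess_series(series), "series must be a charge_excess_series")
  stop_unless(is_ligand_spectrum(spectrum), "spectrum must be a ligand_spectrum")
  if (nrow(series) < 1) stop("empty charge-excess series", call. = FALSE)
  if (is.null(config)) config <- attr(series, "config")
  pred <- forward_model(spectrum, series$pH, config = config)
  d <- series$Q - pred
  qrange <- diff(range(series$Q))
  thr <- pass_fraction * qrange
  structure(list(rmse = sqrt(mean(d^2)),
                 max_abs_diff = max(abs(d)),
                 n_compared = nrow(series),
                 overlap_pH_span = range(series$pH),
                 pass_flag = sqrt(mean(d^2)) <= thr,
                 threshold = thr),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement: rmse %.4g, max |diff| %.4g over %d points (pH %.2f-%.2f) -> %s\n",
              x$rmse, x$max_abs_diff, x$n_compared,
              x$overlap_pH_span[1], x$overlap_pH_span[2],
              if (isTRUE(x$pass_flag)) "PASS" else "FAIL"))
  invisible(x)
}
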