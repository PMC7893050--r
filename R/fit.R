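#' Resample a charge-excess series onto the fit grid
#'
#' Sorts the series by pH, averages duplicate pH readings, and linearly
#' interpolates Q at the grid pH values that fall inside the measured span.
#' Grid points outside the span are omitted, never extrapolated. A series
#' already sampled at grid pH values passes through unchanged at those
#' points.
#'
#' @param series A \code{\link{charge_excess_series}}.
#' @param grid A \code{\link{pka_grid}} (its values double as the pH
#'   evaluation grid).
#' @return A \code{\link{charge_excess_series}} at the retained grid pHs.
#' @export
resample_to_fit_grid <- function(series, grid = pka_grid()) {
  stop_unless(is_charge_excess_series(series), "series must be a charge_excess_series")
  stop_unless(is_pka_grid(grid), "grid must be a pka_grid")
  ord <- order(series$pH)
  pH <- series$pH[ord]; Q <- series$Q[ord]
  if (anyDuplicated(pH)) {
    Q <- as.vector(tapply(Q, pH, mean))
    pH <- sort(unique(pH))
  }
  if (length(pH) < 2) stop("fewer than 2 usable points after duplicate collapse",
                           call. = FALSE)
  keep <- as.numeric(grid) >= pH[1] & as.numeric(grid) <= pH[length(pH)]
  if (sum(keep) < 1) stop("no grid pH values inside the measured pH span",
                          call. = FALSE)
  xout <- as.numeric(grid)[keep]
  Qi <- stats::approx(pH, Q, xout = xout, ties = "ordered")$y
  charge_excess_series(xout, Qi,
                       sample_id = attr(series, "sample_id"),
                       replicate_id = attr(series, "replicate_id"),
                       direction = attr(series, "direction"),
                       config = attr(series, "config"))
}

#' Fit a discrete ligand spectrum by the linear programming method (LPM)
#'
#' Inverts a charge-excess series into concentrations of monoprotic ligands
#' on a fixed pKa grid by minimizing the sum of absolute residuals
#' sum_j |Q_obs,j - Q_pred,j| subject to L_Ti >= 0, with the intercept S
#' free in sign. The L1 objective is linearized with per-point slack
#' variables and solved exactly by a deterministic simplex method.
#'
#' By default the series is first resampled onto the grid pH values
#' (\code{\link{resample_to_fit_grid}}); with \code{resample = FALSE} the fit
#' uses the raw measured points whose pH lies within the grid span.
#'
#' @param series A \code{\link{charge_excess_series}} (Q in mol/g).
#' @param grid A \code{\link{pka_grid}} of candidate sites.
#' @param resample Resample onto the grid pH values first? Default TRUE.
#' @param report_threshold Sites fitted below this concentration (mol/g,
#'   default 1e-6) are reported as zero; suppresses numerically idle
#'   vertices of the LP.
#' @param config Optional \code{\link{vessel_config}} for the activity model
#'   used in the design matrix; taken from the series attributes when
#'   available.
#' @return A list of class \code{lpm_fit} with elements \code{spectrum}
#'   (a \code{\link{ligand_spectrum}}) and \code{diagnostics} (list:
#'   \code{objective_value} -- the optimal LP objective, sum of absolute
#'   residuals before thresholding; \code{per_point_residuals};
#'   \code{rmse}; \code{n_active_sites}; \code{solver_status};
#'   \code{n_points}; \code{pH}).
#' @examples
#' truth <- ligand_spectrum(c(5, 8.4), c(2e-4, 4e-4), S = 1e-5)
#' g <- pka_grid()
#' ser <- charge_excess_series(as.numeric(g), forward_model(truth, as.numeric(g)))
#' fit <- fit_lpm(ser, g)
#' fit$spectrum
#' @export
fit_lpm <- function(series, grid = pka_grid(), resample = TRUE,
                    report_threshold = 1e-6, config = NULL) {
  stop_unless(is_charge_excess_series(series), "series must be a charge_excess_series")
  stop_unless(is_pka_grid(grid), "grid must be a pka_grid")
  if (is.null(config)) config <- attr(series, "config")

  if (resample) {
    use <- resample_to_fit_grid(series, grid)
  } else {
    keep <- series$pH >= attr(grid, "start") - 1e-9 &
      series$pH <= attr(grid, "stop") + 1e-9
    use <- series[keep, , drop = FALSE]
  }
  if (nrow(use) < 2) stop("need at least 2 usable points within the grid pH span",
                          call. = FALSE)

  h <- if (is.null(config)) 10^(-use$pH) else proton_concentration(use$pH, config)
  Xocc <- occupancy_matrix(h, as.numeric(grid))
  X <- cbind(Xocc, 1)                       # last column: intercept S
  nsite <- length(grid)
  sol <- l1_fit(X, use$Q, nonneg = c(rep(TRUE, nsite), FALSE))

  if (sol$status != "optimal") {
    return(structure(list(
      spectrum = NULL,
      diagnostics = list(objective_value = NA_real_,
                         per_point_residuals = NULL, rmse = NA_real_,
                         n_active_sites = NA_integer_,
                         solver_status = "failed",
                         n_points = nrow(use), pH = use$pH)),
      class = "lpm_fit"))
  }

  L <- sol$coef[seq_len(nsite)]
  S <- sol$coef[nsite + 1L]
  L[L < report_threshold] <- 0
  spectrum <- ligand_spectrum(as.numeric(grid), L, S)
  res <- use$Q - forward_model(spectrum, use$pH, config = config)
  structure(list(
    spectrum = spectrum,
    diagnostics = list(objective_value = sol$objective,
                       per_point_residuals = res,
                       rmse = sqrt(mean(res^2)),
                       n_active_sites = sum(L > 0),
                       solver_status = "optimal",
                       n_points = nrow(use),
                       pH = use$pH)),
    class = "lpm_fit")
}

#' @export
print.lpm_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("LPM fit: %s, %d points, objective %.4g, rmse %.4g, %d active site(s)\n",
              d$solver_status, d$n_points, d$objective_value, d$rmse,
              d$n_active_sites))
  if (!is.null(x$spectrum)) print(x$spectrum)
  invisible(x)
}
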