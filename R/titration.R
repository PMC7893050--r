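#' Construct a titration curve
#'
#' A titration curve is one run (one direction) of a potentiometric titration
#' of one EPS sample replicate: an ordered set of cumulative titrant volumes
#' and the pH measured after each addition.
#'
#' Within a curve exactly one of the two cumulative volumes may vary (the
#' titrant being dispensed) and it must be strictly increasing; the other is
#' held constant (for example an acid pre-dose before a base-direction run,
#' or the full base charge before a reverse acid-direction run).
#'
#' @param sample_id Sample identifier (e.g. site/season label).
#' @param replicate_id Replicate identifier within the sample.
#' @param direction \code{"forward"} (base-direction, pH increasing) or
#'   \code{"reverse"} (acid-direction, pH decreasing).
#' @param config A \code{\link{vessel_config}}.
#' @param points A data.frame with columns \code{acid_volume_L},
#'   \code{base_volume_L} (cumulative litres of each titrant) and \code{pH}.
#'   At least 3 rows.
#' @return An object of class \code{titration_curve}.
#' @export
titration_curve <- function(sample_id, replicate_id, direction, config, points) {
  direction <- match.arg(direction, c("forward", "reverse"))
  stop_unless(is_vessel_config(config), "config must be a vessel_config")
  stop_unless(is.data.frame(points) &&
                all(c("acid_volume_L", "base_volume_L", "pH") %in% names(points)),
              "points must have columns acid_volume_L, base_volume_L, pH")
  points <- as.data.frame(points)[, c("acid_volume_L", "base_volume_L", "pH")]
  stop_unless(nrow(points) >= 3, "a titration curve needs at least 3 points")
  stop_unless(all(is.finite(as.matrix(points))), "non-finite values in points")
  stop_unless(all(points$acid_volume_L >= 0) && all(points$base_volume_L >= 0),
              "cumulative titrant volumes must be non-negative")
  stop_unless(all(points$pH > 0 & points$pH < 14), "pH must lie in (0, 14)")

  acid_varies <- diff(range(points$acid_volume_L)) > 0
  base_varies <- diff(range(points$base_volume_L)) > 0
  stop_unless(xor(acid_varies, base_varies),
              "exactly one of acid/base cumulative volume must vary within a curve")
  varying <- if (acid_varies) points$acid_volume_L else points$base_volume_L
  stop_unless(all(diff(varying) > 0),
              "cumulative volume of the dispensed titrant must be strictly increasing")

  structure(
    list(sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         direction = direction,
         config = config,
         points = points),
    class = "titration_curve")
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("Titration curve: sample %s, replicate %s, %s direction\n",
              x$sample_id, x$replicate_id, x$direction))
  cat(sprintf("  %d points, pH %.2f to %.2f\n", nrow(x$points),
              x$points$pH[1], x$points$pH[nrow(x$points)]))
  invisible(x)
}

is_titration_curve <- function(x) inherits(x, "titration_curve")

#' Construct a charge-excess series
#'
#' Holds the observable side of the proton-binding model: for each titration
#' point, the net titratable charge Q per gram of EPS at the measured pH.
#' Usually produced by \code{\link{charge_excess}} rather than directly.
#'
#' @param pH Numeric vector of pH values.
#' @param Q Numeric vector of charge excess values, mol per gram of EPS.
#' @param sample_id,replicate_id,direction Provenance labels.
#' @param config Optional \code{\link{vessel_config}} carried for reference.
#' @return A data.frame of class \code{charge_excess_series} with columns
#'   \code{pH} and \code{Q} (mol/g) and provenance attributes.
#' @export
charge_excess_series <- function(pH, Q, sample_id = "sample",
                                 replicate_id = "1", direction = "forward",
                                 config = NULL) {
  stop_unless(length(pH) == length(Q), "pH and Q must have the same length")
  stop_unless(all(is.finite(Q)), "all Q values must be finite")
  stop_unless(all(is.finite(pH) & pH > 0 & pH < 14), "pH must lie in (0, 14)")
  out <- data.frame(pH = as.numeric(pH), Q = as.numeric(Q))
  attr(out, "sample_id") <- as.character(sample_id)
  attr(out, "replicate_id") <- as.character(replicate_id)
  attr(out, "direction") <- direction
  attr(out, "config") <- config
  class(out) <- c("charge_excess_series", "data.frame")
  out
}

is_charge_excess_series <- function(x) inherits(x, "charge_excess_series")

#' @export
print.charge_excess_series <- function(x, ...) {
  cat(sprintf("Charge-excess series (%s / %s / %s): %d points, pH %.2f-%.2f, Q %.3g to %.3g mol/g\n",
              attr(x, "sample_id"), attr(x, "replicate_id"), attr(x, "direction"),
              nrow(x), min(x$pH), max(x$pH), min(x$Q), max(x$Q)))
  invisible(x)
}
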