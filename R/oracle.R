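#' Exhaustive lattice search for the L1 titration fit (reference oracle)
#'
#' Brute-force minimizer of the LPM objective over a finite lattice of
#' candidate ligand concentrations and intercepts: evaluates
#' sum_j |Q_j - sum_i Ka_i L_i/(Ka_i + [H+]_j) - S| for every combination of
#' \code{L_values} over the sites and every \code{S_values}, and returns the
#' best lattice point. Exponential in the number of sites, so only usable on
#' tiny instances; it exists as an independent check that the simplex-based
#' \code{\link{fit_lpm}} objective is never worse than any lattice point.
#'
#' @param pH,Q Observed pH and charge-excess vectors (equal length).
#' @param pKa Candidate site pKa values (keep to ~3 sites).
#' @param L_values Lattice of candidate concentrations per site
#'   (same units as Q).
#' @param S_values Lattice of candidate intercepts.
#' @return List with \code{objective} (the lattice minimum), \code{L} and
#'   \code{S} at the best lattice point.
#' @export
lattice_l1_search <- function(pH, Q, pKa,
                              L_values = seq(0, 0.5, by = 0.01),
                              S_values = seq(-0.1, 0.1, by = 0.01)) {
  stop_unless(length(pH) == length(Q), "pH and Q must have equal length")
  nsite <- length(pKa)
  stop_unless(nsite >= 1 && nsite <= 4, "lattice search supports 1-4 sites")
  X <- occupancy_matrix(10^(-pH), pKa)
  combos <- as.matrix(expand.grid(rep(list(L_values), nsite)))
  pred <- X %*% t(combos)                       # n_points x n_combos
  best <- Inf; best_i <- NA; best_S <- NA
  for (S in S_values) {
    obj <- colSums(abs(Q - pred - S))
    i <- which.min(obj)
    if (obj[i] < best) { best <- obj[i]; best_i <- i; best_S <- S }
  }
  list(objective = best, L = unname(combos[best_i, ]), S = best_S)
}
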