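# Least-absolute-deviations fit with sign constraints, solved as a linear
# program by a dense primal simplex.
#
# minimize  sum_j |y_j - X beta|_j   subject to  beta_k >= 0 for k in nonneg
#
# Standard form: variables z = (beta+, beta- for free cols, u, v) >= 0 with
#   [X, -X_free, I, -I] z = y,  cost = sum(u) + sum(v).
# The +/- residual slacks give an immediate feasible basis (u_j or v_j per
# sign of y_j), so no phase-1 is needed. The basis inverse is maintained by
# product-form updates with periodic refactorization.
#
# Numerical notes. Titration design columns at adjacent pKa values are
# nearly collinear and optimal bases are heavily degenerate (many exactly
# fitted points), so the pivot rules are chosen for stability: an entering
# column whose transformed pivot candidates are all numerically negligible
# is rejected (it lies in the span of the basis at working precision);
# among near-tied ratio-test rows the largest pivot magnitude wins; and
# Bland's smallest-index rule takes over after a long degenerate stall to
# guarantee termination.

l1_fit <- function(X, y, nonneg = rep(TRUE, ncol(X)),
                   tol = 1e-9, max_iter = NULL) {
  X <- as.matrix(X)
  m <- nrow(X); p <- ncol(X)
  stop_unless(length(y) == m, "X and y are incompatible")
  stop_unless(length(nonneg) == p, "nonneg must have one entry per column of X")
  stop_unless(all(is.finite(X)) && all(is.finite(y)), "non-finite inputs")
  stop_unless(all(colSums(abs(X)) > 0), "design matrix has an all-zero column")

  scale <- max(abs(y))
  if (scale == 0) {
    return(list(coef = numeric(p), residuals = y, objective = 0,
                status = "optimal", iterations = 0L))
  }
  b <- y / scale

  free_idx <- which(!nonneg)
  nf <- length(free_idx)
  # full standard-form matrix: beta+ (p) | beta- (nf) | u (m) | v (m)
  A <- cbind(X, if (nf) -X[, free_idx, drop = FALSE], diag(m), -diag(m))
  N <- p + nf + 2L * m
  cost <- c(rep(0, p + nf), rep(1, 2L * m))

  basis <- ifelse(b >= 0, p + nf + seq_len(m), p + nf + m + seq_len(m))
  Binv <- diag(ifelse(b >= 0, 1, -1))
  xB <- abs(b)

  if (is.null(max_iter)) max_iter <- 500L * (m + p)
  bland_after <- 20L * (m + p)
  piv_tol <- 1e-9
  status <- "max_iter"
  it <- 0L
  obj_prev <- sum(cost[basis] * xB)
  stall <- 0L

  while (it < max_iter) {
    it <- it + 1L
    if (it %% 40L == 0L) {            # refactorize for numerical hygiene
      Binv_new <- tryCatch(solve(A[, basis, drop = FALSE]),
                           error = function(e) NULL)
      if (!is.null(Binv_new)) {
        Binv <- Binv_new
        xB <- pmax(as.vector(Binv %*% b), 0)
      }
    }
    lambda <- crossprod(cost[basis], Binv)          # 1 x m dual row
    d <- cost - as.vector(lambda %*% A)             # reduced costs
    d[basis] <- 0
    use_bland <- stall > bland_after
    cand <- which(d < -tol)
    if (!length(cand)) { status <- "optimal"; break }
    cand <- if (use_bland) cand[order(cand)] else cand[order(d[cand])]
    cand <- cand[seq_len(min(length(cand), 25L))]

    pivoted <- FALSE
    for (j in cand) {
      w <- as.vector(Binv %*% A[, j])
      wmax <- max(abs(w))
      pos <- which(w > piv_tol * max(1, wmax))
      if (!length(pos)) next                         # numerically dependent
      ratio <- xB[pos] / w[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + 1e-9 * (1 + rmin)]
      r <- if (use_bland) ties[which.min(basis[ties])]
           else ties[which.max(w[ties])]             # stability tie-break
      theta <- xB[r] / w[r]
      xB <- xB - theta * w
      xB[xB < 0] <- 0
      xB[r] <- theta
      br <- Binv[r, ] / w[r]
      Binv <- Binv - outer(w, br)
      Binv[r, ] <- br
      basis[r] <- j
      pivoted <- TRUE
      break
    }
    if (!pivoted) { status <- "optimal"; break }     # only negligible pivots

    obj <- sum(cost[basis] * xB)
    if (obj < obj_prev - 1e-15) { stall <- 0L; obj_prev <- obj }
    else stall <- stall + 1L
  }

  z <- numeric(N)
  z[basis] <- xB
  beta <- z[seq_len(p)]
  if (nf) beta[free_idx] <- beta[free_idx] - z[p + seq_len(nf)]
  beta <- beta * scale
  res <- as.vector(y - X %*% beta)
  list(coef = beta,
       residuals = res,
       objective = sum(abs(res)),
       status = status,
       iterations = it)
}
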