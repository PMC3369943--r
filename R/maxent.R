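#' Feasible range of the correlation coefficient for two count marginals
#'
#' Not every correlation is attainable for fixed discrete marginals. The
#' extremes are reached by the comonotone (both counts a non-decreasing
#' function of one common uniform) and countermonotone couplings of the
#' truncated marginals — the Frechet-Hoeffding bounds evaluated on the grid.
#'
#' @param mx,my Marginal specs or rates.
#' @param support A [truncate_support()] grid; computed from the marginals if
#'   omitted.
#' @return An object of class `"correlation_range"` with fields `rho_min` and
#'   `rho_max`.
#' @export
feasible_correlation_range <- function(mx, my, support = NULL) {
  mx <- as_marginal(mx); my <- as_marginal(my)
  if (is.null(support)) support <- truncate_support(mx, my)
  px <- marginal_pmf_vector(mx, support$max_x)
  py <- marginal_pmf_vector(my, support$max_y)
  range_from_marginals(px, py)
}

range_from_marginals <- function(px, py) {
  momx <- pmf_moments(px); momy <- pmf_moments(py)
  if (momx$var <= 0 || momy$var <= 0)
    stop("degenerate marginal: all mass at one point, correlation undefined")
  sd2 <- sqrt(momx$var * momy$var)
  mm <- momx$mean * momy$mean
  exy_hi <- coupling_exy(px, py, decreasing = FALSE)
  exy_lo <- coupling_exy(px, py, decreasing = TRUE)
  structure(list(rho_min = max(-1, (exy_lo - mm) / sd2),
                 rho_max = min(1, (exy_hi - mm) / sd2)),
            class = "correlation_range")
}

#' @export
print.correlation_range <- function(x, ...) {
  cat(sprintf("Feasible correlation range: [%.6f, %.6f]\n",
              x$rho_min, x$rho_max))
  invisible(x)
}

# E[XY] under the quantile coupling: X = Qx(U), Y = Qy(U) (comonotone) or
# Y = Qy(1-U) (countermonotone). Integrates over the merged CDF breakpoints.
coupling_exy <- function(px, py, decreasing = FALSE) {
  if (decreasing) py <- rev(py)
  cx <- cumsum(px); cy <- cumsum(py)
  cx[length(cx)] <- 1; cy[length(cy)] <- 1
  breaks <- sort(unique(c(0, cx, cy)))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  len <- diff(breaks)
  qx <- findInterval(mids, cx) # value of X on each interval
  qy <- findInterval(mids, cy)
  if (decreasing) qy <- (length(py) - 1) - qy
  sum(len * qx * qy)
}

#' Fit the maximum entropy distribution with fixed marginals and correlation
#'
#' Among all bivariate distributions on the truncated grid with the given
#' (truncated, renormalized) Poisson marginals and Pearson correlation `rho`,
#' finds the one of maximal Shannon entropy. The solution has the exponential
#' family form \eqn{p_{ij} \propto r_i c_j e^{\theta i j}}: for a trial value
#' of the interaction exponent \eqn{\theta}, the row/column factors are
#' obtained by iterative proportional fitting to the marginals, and
#' \eqn{\theta} itself is root-solved so that \eqn{E[XY]} matches the value
#' implied by `rho`.
#'
#' @param mx,my Marginal specs (or rates).
#' @param rho Target Pearson correlation; must lie inside
#'   [feasible_correlation_range()].
#' @param support Optional [truncate_support()] grid.
#' @param constraint_tol Maximum allowed residual on the marginal and
#'   product-moment constraints.
#' @param truncation_epsilon Passed to [truncate_support()] when `support` is
#'   omitted.
#' @param max_iter Iteration cap for the proportional-fitting inner loop.
#' @param clip_rho If `TRUE`, an infeasible `rho` is clipped to the feasible
#'   range shrunk by a 1e-6 margin instead of raising an error (used inside
#'   the nuisance-parameter search so the optimizer never leaves its domain).
#' @return An object of class `"maxent_model"` with fields `rate_x`, `rate_y`,
#'   `rho` (the value actually fitted), `support`, `theta`, `row_factors`,
#'   `col_factors`, `pmf` (a [bivariate_pmf()]), `residual`, and `clipped`.
#' @examples
#' m <- fit_maxent(3, 3, 0.2)
#' pearson_correlation(m$pmf)
#' @export
fit_maxent <- function(mx, my, rho, support = NULL,
                       constraint_tol = 1e-9, truncation_epsilon = 1e-10,
                       max_iter = 1e4, clip_rho = FALSE) {
  mx <- as_marginal(mx); my <- as_marginal(my)
  if (!is.finite(rho) || abs(rho) >= 1)
    stop("invalid parameter: `rho` must be finite and inside (-1, 1)")
  if (is.null(support)) support <- truncate_support(mx, my, truncation_epsilon)
  px <- marginal_pmf_vector(mx, support$max_x)
  py <- marginal_pmf_vector(my, support$max_y)
  rng <- range_from_marginals(px, py)
  clipped <- FALSE
  if (rho <= rng$rho_min || rho >= rng$rho_max) {
    if (!clip_rho)
      stop(sprintf(
        "infeasible correlation: rho = %g outside attainable range (%.6f, %.6f)",
        rho, rng$rho_min, rng$rho_max))
    rho <- min(max(rho, rng$rho_min + 1e-6), rng$rho_max - 1e-6)
    clipped <- TRUE
  }

  momx <- pmf_moments(px); momy <- pmf_moments(py)
  target_exy <- rho * sqrt(momx$var * momy$var) + momx$mean * momy$mean
  i <- 0:support$max_x; j <- 0:support$max_y
  ij <- outer(i, j)

  ipf <- function(theta) {
    # per-row shift keeps the kernel finite and every row/column nonzero at
    # extreme theta (the shift is absorbed by the row factors)
    logK <- theta * ij
    K <- exp(logK - apply(logK, 1, max))
    rvec <- px / rowSums(K)
    cvec <- rep(1, length(py))
    for (it in seq_len(max_iter)) {
      P <- K * outer(rvec, cvec)
      cvec <- cvec * (py / colSums(P))
      P <- K * outer(rvec, cvec)
      rvec <- rvec * (px / rowSums(P))
      # rebalance the scale ambiguity between the two factor vectors
      sc <- max(rvec)
      rvec <- rvec / sc
      cvec <- cvec * sc
      P <- K * outer(rvec, cvec)
      if (any(!is.finite(P)))
        stop("ipf numeric failure: factor dynamic range exceeds double precision")
      if (max(abs(rowSums(P) - px)) < constraint_tol &&
          max(abs(colSums(P) - py)) < constraint_tol)
        return(list(P = P, r = rvec, cvec = cvec, iter = it))
    }
    stop(sprintf(paste0(
      "maxent solver did not converge after %d iterations ",
      "(marginal residual %.3g)"), max_iter, max(abs(rowSums(P) - px))))
  }

  exy_at <- function(theta) sum(ij * ipf(theta)$P)

  if (abs(rho) < .Machine$double.eps) {
    theta <- 0
  } else {
    # E[XY] is increasing in theta; expand a bracket then root-solve. Near
    # the Frechet boundary the exponent diverges and the factor products
    # leave double precision, so expansion stops at the last numerically
    # stable theta.
    f <- function(th) tryCatch(exy_at(th) - target_exy,
                               error = function(e) NA_real_)
    lo <- -0.25; hi <- 0.25
    flo <- f(lo); fhi <- f(hi)
    while (!is.na(flo) && flo > 0) {
      nxt <- f(lo * 2)
      if (is.na(nxt)) break
      lo <- lo * 2; flo <- nxt
    }
    while (!is.na(fhi) && fhi < 0) {
      nxt <- f(hi * 2)
      if (is.na(nxt)) break
      hi <- hi * 2; fhi <- nxt
    }
    if (is.na(flo) || is.na(fhi))
      stop("maxent solver: numeric failure at moderate interaction strength")
    if (flo > 0 || fhi < 0) {
      if (!clip_rho)
        stop(sprintf(paste0(
          "maxent solver: requested correlation %.4g is beyond the ",
          "numerically representable dependence strength"), rho))
      # best-effort extreme-dependence member of the family
      theta <- if (fhi < 0) hi else lo
    } else {
      theta <- stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
    }
  }
  sol <- ipf(theta)
  achieved_exy <- sum(ij * sol$P)
  if (abs(achieved_exy - target_exy) > 1e-6) {
    # boundary best-effort fit: record the correlation actually achieved
    rho <- (achieved_exy - momx$mean * momy$mean) /
      sqrt(momx$var * momy$var)
    target_exy <- achieved_exy
    clipped <- TRUE
  }
  resid <- max(abs(rowSums(sol$P) - px), abs(colSums(sol$P) - py),
               abs(achieved_exy - target_exy))
  structure(list(rate_x = mx$rate, rate_y = my$rate, rho = rho,
                 support = support, theta = theta,
                 row_factors = sol$r, col_factors = sol$cvec,
                 pmf = bivariate_pmf(sol$P, normalize = TRUE),
                 residual = resid, clipped = clipped,
                 constraint_tol = constraint_tol),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat("Maximum entropy spike-count model\n")
  cat(sprintf("  Poisson rates: %.4g, %.4g; correlation: %.4g%s\n",
              x$rate_x, x$rate_y, x$rho,
              if (x$clipped) " (clipped to feasible range)" else ""))
  cat(sprintf("  support {0..%d} x {0..%d}; theta = %.6g\n",
              x$support$max_x, x$support$max_y, x$theta))
  cat(sprintf("  entropy %.4f bits; constraint residual %.2g\n",
              entropy(x$pmf), x$residual))
  invisible(x)
}
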