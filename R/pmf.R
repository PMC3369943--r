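#' Poisson marginal specification
#'
#' Describes a single neuron's spike-count distribution within one time bin.
#' Only the Poisson family is shipped; the `family` field exists so that other
#' count families can be plugged in without changing downstream code.
#'
#' @param rate Positive real; expected spike count per bin (dimensionless,
#'   i.e. firing rate times bin length).
#' @param family Marginal family; currently only `"poisson"`.
#' @return An object of class `"marginal_spec"`.
#' @examples
#' poisson_marginal(3)
#' @export
poisson_marginal <- function(rate, family = "poisson") {
  family <- match.arg(family, "poisson")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("invalid parameter: `rate` must be a single finite positive number")
  structure(list(family = family, rate = rate), class = "marginal_spec")
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat(sprintf("Marginal spec: %s(rate = %g)\n", x$family, x$rate))
  invisible(x)
}

as_marginal <- function(x) {
  if (inherits(x, "marginal_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(poisson_marginal(x))
  stop("invalid parameter: expected a marginal_spec or a single rate")
}

#' Truncate the support of a pair of count marginals
#'
#' Count marginals have unbounded support; all table computations happen on a
#' finite grid \eqn{\{0,\dots,K_x\}\times\{0,\dots,K_y\}}. Each bound is the
#' smallest K whose cumulative marginal mass reaches `1 - truncation_epsilon`,
#' with a floor of 1, so that the discarded mass is negligible for any
#' realistic sample size.
#'
#' @param mx,my Marginal specs (see [poisson_marginal()]) or plain rates.
#' @param truncation_epsilon Mass allowed beyond the truncation point, in
#'   (0, 1e-4].
#' @return An object of class `"truncated_support"` with integer fields
#'   `max_x` and `max_y`.
#' @examples
#' truncate_support(poisson_marginal(3), poisson_marginal(3))
#' @export
truncate_support <- function(mx, my, truncation_epsilon = 1e-10) {
  if (!is.numeric(truncation_epsilon) || length(truncation_epsilon) != 1L ||
      truncation_epsilon <= 0 || truncation_epsilon > 1e-4)
    stop("invalid parameter: `truncation_epsilon` must be in (0, 1e-4]")
  mx <- as_marginal(mx); my <- as_marginal(my)
  structure(list(max_x = marginal_qbound(mx, truncation_epsilon),
                 max_y = marginal_qbound(my, truncation_epsilon)),
            class = "truncated_support")
}

marginal_qbound <- function(m, eps) {
  k <- stats::qpois(1 - eps, m$rate)
  # qpois can land one short at extreme tails; walk up until the CDF clears
  while (stats::ppois(k, m$rate) < 1 - eps) k <- k + 1L
  max(1L, as.integer(k))
}

#' @export
print.truncated_support <- function(x, ...) {
  cat(sprintf("Truncated support: {0..%d} x {0..%d}\n", x$max_x, x$max_y))
  invisible(x)
}

support_from_dims <- function(nx, ny) {
  structure(list(max_x = as.integer(nx) - 1L, max_y = as.integer(ny) - 1L),
            class = "truncated_support")
}

# Truncated, renormalized marginal pmf on 0..K.
marginal_pmf_vector <- function(m, K) {
  m <- as_marginal(m)
  p <- stats::dpois(0:K, m$rate)
  s <- sum(p)
  if (s <= 0) stop("invalid parameter: marginal mass vanishes on the support")
  p / s
}

#' Bivariate probability table on a truncated count grid
#'
#' The universal currency of the package: a probability mass function on
#' \eqn{\{0,\dots,K_x\}\times\{0,\dots,K_y\}} stored as a matrix whose rows
#' index the first count and whose columns index the second.
#'
#' @param probs Nonnegative numeric matrix summing to 1 (within 1e-12).
#' @param normalize If `TRUE`, rescale `probs` to sum to exactly 1 first.
#' @return An object of class `"bivariate_pmf"`: the matrix itself with the
#'   class attached; `dim(x) - 1` recovers the support bounds.
#' @examples
#' p <- bivariate_pmf(matrix(0.25, 2, 2))
#' entropy(p)
#' @export
bivariate_pmf <- function(probs, normalize = FALSE) {
  if (!is.matrix(probs) || !is.numeric(probs))
    stop("invalid parameter: `probs` must be a numeric matrix")
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("invalid parameter: probabilities must be finite and nonnegative")
  if (normalize) probs <- probs / sum(probs)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("invalid parameter: probabilities must sum to 1 within 1e-12")
  structure(probs, class = "bivariate_pmf")
}

#' @export
print.bivariate_pmf <- function(x, ...) {
  cat(sprintf("Bivariate pmf on {0..%d} x {0..%d}\n",
              nrow(x) - 1L, ncol(x) - 1L))
  cat(sprintf("  entropy %.4f bits, correlation %.4f\n",
              entropy(x), pearson_correlation(x)))
  invisible(x)
}

pmf_support <- function(p) support_from_dims(nrow(p), ncol(p))

#' Marginal distributions of a bivariate table
#'
#' @param p A [bivariate_pmf()].
#' @param margin 1 for the row (x) marginal, 2 for the column (y) marginal.
#' @return Numeric probability vector over `0..K`.
#' @export
marginal_pmf <- function(p, margin) {
  stopifnot(margin %in% c(1, 2))
  if (margin == 1) rowSums(p) else colSums(p)
}

#' Shannon entropy in bits
#'
#' Computes \eqn{-\sum p \log_2 p} with the convention \eqn{0 \log 0 = 0}.
#' Accepts a [bivariate_pmf()] or any numeric probability vector/matrix.
#'
#' @param p Probabilities.
#' @return Entropy in bits.
#' @export
entropy <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# first two moments of a pmf vector on 0..K
pmf_moments <- function(p) {
  k <- seq_along(p) - 1
  mu <- sum(k * p)
  v <- sum(k * k * p) - mu^2
  list(mean = mu, var = v)
}

#' Pearson correlation coefficient of a bivariate table
#'
#' Exact product-moment correlation computed from the table:
#' \eqn{(E[XY] - E[X]E[Y]) / \sqrt{Var[X] Var[Y]}}.
#'
#' @param p A [bivariate_pmf()] (or plain probability matrix).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_correlation <- function(p) {
  px <- rowSums(p); py <- colSums(p)
  mx <- pmf_moments(px); my <- pmf_moments(py)
  if (mx$var <= 0 || my$var <= 0)
    stop("degenerate marginal: zero variance, correlation undefined")
  i <- seq_len(nrow(p)) - 1; j <- seq_len(ncol(p)) - 1
  exy <- sum(outer(i, j) * p)
  r <- (exy - mx$mean * my$mean) / sqrt(mx$var * my$var)
  min(1, max(-1, r))
}

# E[XY] of a table
pmf_exy <- function(p) {
  i <- seq_len(nrow(p)) - 1; j <- seq_len(ncol(p)) - 1
  sum(outer(i, j) * p)
}

#' Trial-aligned sample of count pairs
#'
#' @param x,y Nonnegative integer vectors of equal length, one entry per
#'   trial.
#' @param stimulus Optional vector of stimulus labels aligned with the trials
#'   (needed for the mutual-information divergence).
#' @return An object of class `"count_pairs"`: a data frame with columns
#'   `x`, `y` and optionally `stimulus`.
#' @examples
#' count_pairs(c(1, 0, 2), c(0, 0, 3))
#' @export
count_pairs <- function(x, y, stimulus = NULL) {
  if (length(x) != length(y) || length(x) < 1L)
    stop("invalid parameter: `x` and `y` must be nonempty and equal length")
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y)))
    stop("invalid parameter: counts must be nonnegative integers")
  d <- data.frame(x = as.integer(x), y = as.integer(y))
  if (!is.null(stimulus)) {
    if (length(stimulus) != length(x))
      stop("labeling error: `stimulus` must align with the count pairs")
    d$stimulus <- as.character(stimulus)
  }
  class(d) <- c("count_pairs", "data.frame")
  d
}

#' @export
print.count_pairs <- function(x, ...) {
  cat(sprintf("Count pair sample: n = %d%s\n", nrow(x),
              if (!is.null(x$stimulus))
                sprintf(", %d stimuli", length(unique(x$stimulus))) else ""))
  invisible(x)
}

#' Draw i.i.d. count pairs from a bivariate table
#'
#' Inverse-CDF sampling on the flattened table; reproducible given `seed`.
#'
#' @param p A [bivariate_pmf()].
#' @param n Number of pairs to draw.
#' @param seed Optional integer seed.
#' @return A [count_pairs()] sample.
#' @export
sample_pmf <- function(p, n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("invalid parameter: `n` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  k <- length(p)
  idx <- sample.int(k, size = n, replace = TRUE, prob = as.numeric(p))
  i <- (idx - 1L) %% nrow(p)           # x count
  j <- (idx - 1L) %/% nrow(p)          # y count
  count_pairs(i, j)
}

#' Empirical distribution of a count-pair sample
#'
#' Entry (i, j) is the fraction of trials with counts exactly (i, j). If the
#' sample contains counts outside `support`, the grid is expanded to cover
#' them (a reference table compared against it must be padded likewise).
#'
#' @param s A [count_pairs()] sample.
#' @param support A [truncate_support()] grid.
#' @return A [bivariate_pmf()] whose entries are multiples of `1/n`.
#' @export
empirical_pmf <- function(s, support) {
  nx <- max(support$max_x, max(s$x)) + 1L
  ny <- max(support$max_y, max(s$y)) + 1L
  flat <- s$y * nx + s$x + 1L
  tab <- matrix(tabulate(flat, nbins = nx * ny), nx, ny)
  bivariate_pmf(tab / nrow(s))
}

# Pad a table with zero rows/columns up to the given dimensions.
pad_pmf <- function(p, nx, ny) {
  if (nrow(p) >= nx && ncol(p) >= ny) return(p)
  out <- matrix(0, max(nrow(p), nx), max(ncol(p), ny))
  out[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  bivariate_pmf(out)
}
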