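#' Likelihood ratio test of the maximum entropy hypothesis
#'
#' Compares the full model — the saturated multinomial over the count grid,
#' whose maximum likelihood estimate is the empirical frequency table — with
#' the reduced maximum entropy model (Poisson marginals plus correlation,
#' three free parameters). The statistic is
#' \eqn{\Lambda = 2(\ell_{full} - \ell_{ME})}, asymptotically chi-square with
#' degrees of freedom equal to the number of additional free parameters of
#' the full model: (grid cells - 1) - 3. The chi-square approximation is an
#' asymptotic one and is unreliable at small sample sizes — the motivation
#' for the exact Monte Carlo test in [run_test()].
#'
#' @param data A [count_pairs()] sample with `n >= 2`.
#' @param support Optional [truncate_support()] grid; defaults to the grid of
#'   the fitted model expanded to cover the data.
#' @return An object of class `"lr_test"` with fields `statistic`, `df`,
#'   `p_value`, `loglik_full`, `loglik_me`, `ml_params`.
#' @export
lr_test <- function(data, support = NULL) {
  n <- nrow(data)
  if (n < 2L) stop("invalid parameter: need at least 2 observations")
  init <- init_nuisance(list(data))[[1L]]

  loglik_me <- function(par) {
    rx <- exp(par[1]); ry <- exp(par[2]); rho <- tanh(par[3])
    m <- try(fit_maxent(rx, ry, rho, clip_rho = TRUE), silent = TRUE)
    if (inherits(m, "try-error")) return(-1e10)
    P <- pad_pmf(m$pmf, max(data$x) + 1L, max(data$y) + 1L)
    ll <- sum(log(pmax(P[cbind(data$x + 1L, data$y + 1L)], 1e-300)))
    if (!is.finite(ll)) -1e10 else ll
  }
  start <- c(log(init$rate_x), log(init$rate_y),
             atanh(min(max(init$rho, -0.99), 0.99)))
  opt <- stats::optim(start, loglik_me, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 400))
  ml <- list(rate_x = exp(opt$par[1]), rate_y = exp(opt$par[2]),
             rho = tanh(opt$par[3]))
  me_model <- fit_maxent(ml$rate_x, ml$rate_y, ml$rho, clip_rho = TRUE)
  ml$rho <- me_model$rho

  # saturated-model support: the probability table of the fitted model
  # (expanded to cover the data). The multinomial's free-parameter count is
  # the full table size, which makes the chi-square reference very
  # conservative at small n — the regime where the exact Monte Carlo test
  # is the appropriate tool.
  if (is.null(support))
    support <- support_from_dims(
      max(nrow(me_model$pmf), max(data$x) + 1L),
      max(ncol(me_model$pmf), max(data$y) + 1L))
  k <- (support$max_x + 1L) * (support$max_y + 1L)

  emp <- empirical_pmf(data, support)
  pe <- as.numeric(emp); pe <- pe[pe > 0]
  ll_full <- n * sum(pe * log(pe))
  ll_me <- opt$value
  stat <- max(2 * (ll_full - ll_me), 0)
  df <- max((k - 1L) - 3L, 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 loglik_full = ll_full, loglik_me = ll_me,
                 ml_params = ml, n = n),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat("Likelihood ratio test: multinomial vs maximum entropy model\n")
  cat(sprintf("  statistic = %.4g on %d df, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' The step-up procedure: order the p-values ascending, find the largest k
#' with \eqn{p_{(k)} \le k\alpha/m}, and reject exactly the k smallest. The
#' rejection set is always a prefix of the ascending order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level.
#' @return An object of class `"fdr_result"` with fields `raw_p`, `rejected`
#'   (logical, aligned with the input), `threshold_index` (k above; 0 when
#'   nothing is rejected), and `alpha`.
#' @export
bh_procedure <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    stop("invalid parameter: p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  ok <- which(ps <= seq_len(m) * alpha / m)
  k <- if (length(ok)) max(ok) else 0L
  rejected <- rep(FALSE, m)
  if (k > 0L) rejected[ord[seq_len(k)]] <- TRUE
  structure(list(raw_p = p_values, rejected = rejected,
                 threshold_index = k, alpha = alpha),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("Benjamini-Hochberg at FDR %g: %d of %d rejected\n",
              x$alpha, sum(x$rejected), length(x$raw_p)))
  invisible(x)
}

#' Single-neuron Monte Carlo goodness-of-fit test for Poisson counts
#'
#' Univariate analogue of the maximum entropy test: the reference is the
#' (truncated) Poisson distribution, the statistic is the Kullback-Leibler
#' divergence of the empirical count histogram from the reference pmf, the
#' p-value is the tie-broken Monte Carlo rank, and it is maximized over the
#' single nuisance parameter (the rate) by a one-dimensional anneal. The KL
#' statistic (rather than an entropy difference) is used because the free
#' rate could always be tuned to equalize the two entropies, which would
#' leave an entropy-difference statistic with no power against non-Poisson
#' count histograms. A sample that is all zeros admits a degenerate fit and
#' returns p = 1.
#'
#' @param counts Nonnegative integer vector.
#' @param n_mc Number of Monte Carlo samples.
#' @param anneal An [anneal_config()].
#' @param seed Optional integer seed.
#' @return The worst-case p-value.
#' @export
poisson_gof_mc <- function(counts, n_mc = 199L,
                           anneal = anneal_config(steps = 50L),
                           seed = NULL) {
  if (length(counts) < 1L) stop("invalid parameter: empty count vector")
  if (!is.null(seed)) set.seed(seed)
  if (mean(counts) == 0) return(1)
  n <- length(counts)

  kl_bits <- function(V, ref) {
    # per-column KL divergence of proportion columns V from ref (bits)
    L <- V * log2(V / ref)
    L[V == 0] <- 0
    colSums(L)
  }
  eval_rate <- function(rate) {
    K <- max(marginal_qbound(poisson_marginal(rate), 1e-10), max(counts))
    ref <- marginal_pmf_vector(poisson_marginal(rate), K)
    emp <- tabulate(counts + 1L, nbins = K + 1L) / n
    d0 <- kl_bits(cbind(emp), ref)
    V <- sample_prop_matrix(ref, K + 1L, n, n_mc)
    mc_p_value(d0, kl_bits(V, ref))
  }

  rate <- mean(counts)
  se <- sqrt(rate / n)
  box <- c(max(rate - anneal$search_width * se, 1e-3),
           rate + anneal$search_width * se)
  if (anneal$common_rng) {
    mc_seed <- sample.int(.Machine$integer.max, 1L)
    eval_raw <- eval_rate
    eval_rate <- function(r) { set.seed(mc_seed); eval_raw(r) }
  }
  p_cur <- eval_rate(rate)
  best <- p_cur
  temp <- anneal$initial_temperature
  for (s in seq_len(anneal$steps)) {
    prop <- min(max(rate + stats::rnorm(1, 0, anneal$rate_scale * se),
                    box[1]), box[2])
    p_new <- eval_rate(prop)
    if (p_new >= p_cur || stats::runif(1) < exp((p_new - p_cur) / temp)) {
      rate <- prop; p_cur <- p_new
      best <- max(best, p_new)
    }
    temp <- temp * anneal$cooling_factor
  }
  best
}

#' Kolmogorov-Smirnov test of the Poisson-process hypothesis via time rescaling
#'
#' Rescales the interspike intervals by the integrated (piecewise-constant)
#' rate; under a correctly specified Poisson process the rescaled intervals
#' are unit-exponential, so \eqn{1 - e^{-\tau}} is Uniform(0, 1) and a
#' one-sample Kolmogorov-Smirnov test applies.
#'
#' @param train A [spike_train()] (or sorted numeric vector of spike times in
#'   seconds with a `duration` attribute).
#' @param rate_per_bin Rate (Hz) in each consecutive bin of width `bin_s`; a
#'   single number gives a homogeneous rate. Defaults to the train's overall
#'   mean rate.
#' @param bin_s Bin width in seconds for the piecewise-constant rate.
#' @return The KS p-value.
#' @export
time_rescaling_ks <- function(train, rate_per_bin = NULL, bin_s = NULL) {
  times <- as.numeric(train)
  duration <- attr(train, "duration")
  if (length(times) < 2L)
    stop("insufficient data: need at least 2 spikes")
  if (is.null(rate_per_bin)) {
    rate_per_bin <- length(times) / duration
    bin_s <- duration
  }
  if (is.null(bin_s)) stop("invalid parameter: `bin_s` required with a rate profile")
  # integrated rate Lambda(t) under the piecewise-constant profile
  edges <- seq(0, by = bin_s, length.out = length(rate_per_bin) + 1L)
  cum <- c(0, cumsum(rate_per_bin * bin_s))
  Lambda <- function(t) {
    i <- pmin(pmax(findInterval(t, edges), 1L), length(rate_per_bin))
    cum[i] + (t - edges[i]) * rate_per_bin[i]
  }
  tau <- diff(Lambda(times))
  u <- 1 - exp(-tau)
  stats::ks.test(u, "punif")$p.value
}
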