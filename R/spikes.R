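#' Spike train object
#'
#' @param times Strictly increasing nonnegative spike times in seconds.
#' @param duration Recording duration in seconds; all times must lie in
#'   `[0, duration]`.
#' @return Numeric vector of class `"spike_train"` with a `duration`
#'   attribute.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1L)
    stop("invalid parameter: spike times must be strictly increasing")
  if (length(times) && (min(times) < 0 || max(times) > duration))
    stop("invalid parameter: spike times must lie in [0, duration]")
  structure(times, duration = duration, class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g s (mean rate %.3g Hz)\n",
              length(x), attr(x, "duration"),
              length(x) / attr(x, "duration")))
  invisible(x)
}

#' Simulate a gamma renewal process
#'
#' Interspike intervals are i.i.d. Gamma with shape `shape` and mean
#' `1/rate_hz` (so the mean rate is `rate_hz` regardless of the shape).
#' `shape = 1` gives exponential intervals, i.e. a Poisson process;
#' `shape > 1` produces a relative refractory period, making the train more
#' regular (interval coefficient of variation `1/sqrt(shape)`) and inducing
#' autocorrelation in binned counts. The process is an ordinary renewal
#' process started at time 0 (the first interval is drawn from the same
#' distribution).
#'
#' @param rate_hz Mean firing rate in Hz.
#' @param shape Gamma shape parameter, at least 1.
#' @param duration_s Duration of the simulated train in seconds.
#' @param seed Optional integer seed.
#' @return A [spike_train()].
#' @export
simulate_gamma_train <- function(rate_hz, shape = 1, duration_s, seed = NULL) {
  if (duration_s <= 0) stop("invalid parameter: `duration_s` must be positive")
  if (shape < 1)
    stop("unsupported parameter: `shape` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  times <- numeric(0)
  t_last <- 0
  chunk <- max(16L, ceiling(rate_hz * duration_s * 1.25))
  repeat {
    isi <- stats::rgamma(chunk, shape = shape, rate = shape * rate_hz)
    times <- c(times, t_last + cumsum(isi))
    t_last <- times[length(times)]
    if (t_last > duration_s) break
  }
  spike_train(times[times <= duration_s], duration_s)
}

#' Bin a spike train into counts
#'
#' Counts spikes in consecutive left-closed, right-open intervals of width
#' `bin_s` starting at time 0; a trailing partial bin is discarded.
#'
#' @param train A [spike_train()].
#' @param bin_s Bin width in seconds.
#' @return Integer vector of counts, one per complete bin.
#' @export
bin_counts <- function(train, bin_s) {
  if (bin_s <= 0) stop("invalid parameter: `bin_s` must be positive")
  duration <- attr(train, "duration")
  nb <- floor(duration / bin_s + 1e-9)
  if (nb < 1L) return(integer(0))
  idx <- floor(as.numeric(train) / bin_s) + 1L
  idx <- idx[idx <= nb]
  tabulate(idx, nbins = nb)
}

#' Synthetic multi-electrode experiment fixture
#'
#' Generates a labelled spike-count dataset with the design of a typical
#' multi-electrode adaptation experiment: `n_neurons` cells (all pairs are
#' analyzed), two conditions (control/adaptation), 8 stimulus orientations,
#' and a fixed number of repetitions per cell of the design, for each
#' requested count bin size. Per-neuron firing rates are drawn from a bimodal
#' population (a high-rate and a low-rate group); per-pair dependence can be
#' independent, maximum entropy with a linear correlation, or one of the
#' copula mixture families.
#'
#' @param n_neurons Number of recorded cells (default 11, i.e. 55 pairs).
#' @param repetitions Trials per (pair, condition, orientation) cell
#'   (default 42).
#' @param bin_sizes_ms Count bin sizes in milliseconds.
#' @param conditions Condition labels.
#' @param n_orientations Number of stimulus orientations (default 8).
#' @param dependence `"independent"`, `"maxent"`, `"M1"` or `"M2"`.
#' @param dep_params List of dependence parameters: `rho` for `"maxent"`,
#'   `m` (and optionally `rho1`, `copula_weight`) for the mixture families.
#' @param rate_range_high,rate_range_low Uniform ranges (Hz) for the high-
#'   and low-rate populations.
#' @param prop_high Fraction of neurons in the high-rate population.
#' @param seed Optional integer seed.
#' @return A data frame of class `"experiment_fixture"` with columns `pair`,
#'   `neuron_i`, `neuron_j`, `condition`, `orientation`, `bin_ms`, `trial`,
#'   `x`, `y`, plus a `rates_hz` attribute with the per-neuron rates.
#' @export
generate_fixture <- function(n_neurons = 11L, repetitions = 42L,
                             bin_sizes_ms = c(10, 20, 40, 80, 100, 200, 400),
                             conditions = c("control", "adaptation"),
                             n_orientations = 8L,
                             dependence = c("independent", "maxent",
                                            "M1", "M2"),
                             dep_params = list(),
                             rate_range_high = c(20, 35),
                             rate_range_low = c(2, 8),
                             prop_high = 0.5, seed = NULL) {
  dependence <- match.arg(dependence)
  if (repetitions < 1L) stop("invalid parameter: `repetitions` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_high <- round(prop_high * n_neurons)
  rates_hz <- c(stats::runif(n_high, rate_range_high[1], rate_range_high[2]),
                stats::runif(n_neurons - n_high,
                             rate_range_low[1], rate_range_low[2]))
  pairs <- utils::combn(n_neurons, 2L)
  orientations <- seq(0L, by = as.integer(180 / n_orientations),
                      length.out = n_orientations)
  out <- vector("list", 0L)
  for (b in bin_sizes_ms) {
    for (pi in seq_len(ncol(pairs))) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      lx <- rates_hz[i] * b / 1000
      ly <- rates_hz[j] * b / 1000
      tab <- switch(dependence,
        independent = {
          sup <- truncate_support(lx, ly)
          bivariate_pmf(outer(marginal_pmf_vector(poisson_marginal(lx),
                                                  sup$max_x),
                              marginal_pmf_vector(poisson_marginal(ly),
                                                  sup$max_y)))
        },
        maxent = fit_maxent(lx, ly,
                            if (is.null(dep_params$rho)) 0.2
                            else dep_params$rho,
                            clip_rho = TRUE)$pmf,
        build_mixture_model(dependence,
                            m = if (is.null(dep_params$m)) 1 else dep_params$m,
                            rate = lx, rate_y = ly,
                            rho1 = if (is.null(dep_params$rho1)) 0.9
                                   else dep_params$rho1,
                            copula_weight =
                              if (is.null(dep_params$copula_weight)) 0.5
                              else dep_params$copula_weight)$pmf)
      for (cond in conditions) {
        for (ori in orientations) {
          s <- sample_pmf(tab, repetitions)
          out[[length(out) + 1L]] <- data.frame(
            pair = pi, neuron_i = i, neuron_j = j, condition = cond,
            orientation = ori, bin_ms = b, trial = seq_len(repetitions),
            x = s$x, y = s$y)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "rates_hz") <- rates_hz
  attr(res, "dependence") <- dependence
  class(res) <- c("experiment_fixture", "data.frame")
  res
}
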