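#' Derive a reproducible per-cell seed from a base seed
#'
#' Experiment grids run many independent cells (replication x condition);
#' each cell's seed is derived deterministically from the base seed and the
#' cell index by a fixed linear congruential step modulo 2^31 - 1, so any
#' scheduler may execute cells in any order without changing results.
#'
#' @param base_seed Integer base seed.
#' @param index Cell index (1-based).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(base_seed, index) {
  m <- 2147483647
  as.integer(((as.double(base_seed %% m) * 48271 +
                 as.double(index) * 1103515245 + 12345) %% (m - 1)) + 1)
}

binom_ci <- function(k, n, level = 0.95) {
  if (n == 0) return(c(0, 1))
  as.numeric(stats::binom.test(k, n)$conf.int)
}

summary_row <- function(cell, k, n) {
  ci <- binom_ci(k, n)
  cbind(cell, data.frame(rejections = k, replications = n,
                         fraction = k / n, ci_lo = ci[1], ci_hi = ci[2]))
}

#' Type I error study on maximum entropy data
#'
#' Draws datasets from maximum entropy distributions (no higher-order
#' correlations) over a grid of correlation coefficients and tabulates how
#' often the Monte Carlo test falsely rejects. Because the p-value is
#' maximized over the nuisance parameters, the rejection fraction should stay
#' at or below `alpha` for every correlation value.
#'
#' @param rho_grid Correlation coefficients of the generating distributions.
#' @param n Samples per dataset.
#' @param replications Datasets per grid point... replications are spread
#'   round-robin over `rho_grid` when `per_rho = FALSE` (one pooled cell), or
#'   run per grid point when `per_rho = TRUE`.
#' @param rate Poisson rate of both marginals.
#' @param n_mc,alpha,anneal Passed to [run_test()].
#' @param base_seed Base seed for [derive_seed()].
#' @param per_rho Tabulate per correlation value instead of pooled.
#' @return A data frame of rejection fractions with binomial 95% CIs.
#' @export
experiment_type1 <- function(rho_grid = seq(0, 0.5, by = 0.1), n = 100L,
                             replications = 100L, rate = 3, n_mc = 199L,
                             alpha = 0.05, anneal = anneal_config(),
                             base_seed = 1L, per_rho = FALSE) {
  models <- lapply(rho_grid, function(r) fit_maxent(rate, rate, r))
  rejected <- logical(replications)
  rho_used <- numeric(replications)
  for (i in seq_len(replications)) {
    g <- ((i - 1L) %% length(rho_grid)) + 1L
    rho_used[i] <- rho_grid[g]
    seed <- derive_seed(base_seed, i)
    set.seed(seed)
    d <- sample_pmf(models[[g]]$pmf, n)
    rejected[i] <- run_test(d, "entropy_diff", alpha = alpha, n_mc = n_mc,
                            anneal = anneal)$rejected
  }
  if (per_rho) {
    do.call(rbind, lapply(rho_grid, function(r) {
      idx <- rho_used == r
      summary_row(data.frame(rho = r, n = n), sum(rejected[idx]), sum(idx))
    }))
  } else {
    summary_row(data.frame(rho = NA, n = n), sum(rejected), replications)
  }
}

#' Power study on copula mixture data
#'
#' Draws datasets from the M1/M2 copula mixture families over grids of the
#' mixture parameter `m` and the sample size, and tabulates the rejection
#' fraction of the Monte Carlo test. Power should grow with both `m` (the
#' strength of the higher-order correlations) and the sample size, and should
#' be insensitive to whether the linear correlation is 0 (M1) or 0.2 (M2).
#'
#' @param family `"M1"` or `"M2"`.
#' @param m_grid Mixture parameter values.
#' @param n_grid Sample sizes.
#' @param replications Datasets per (m, n) cell.
#' @param rate Poisson rate.
#' @param n_mc,alpha,anneal Passed to [run_test()].
#' @param base_seed Base seed.
#' @return A data frame of rejection fractions per (m, n) cell.
#' @export
experiment_power <- function(family = "M1", m_grid = c(0, 0.5, 1),
                             n_grid = c(50L, 100L), replications = 100L,
                             rate = 3, n_mc = 199L, alpha = 0.05,
                             anneal = anneal_config(), base_seed = 1L) {
  base_model <- build_mixture_model(family, m = 0, rate = rate)
  comps <- list(me_pmf = base_model$me_pmf,
                copula_pmf = base_model$copula_pmf, rho2 = base_model$rho2)
  out <- list()
  cell <- 0L
  for (m in m_grid) {
    tab <- build_mixture_model(family, m = m, rate = rate,
                               components = comps)$pmf
    for (n in n_grid) {
      cell <- cell + 1L
      k <- 0L
      for (i in seq_len(replications)) {
        set.seed(derive_seed(base_seed, cell * 100000L + i))
        d <- sample_pmf(tab, n)
        k <- k + run_test(d, "entropy_diff", alpha = alpha, n_mc = n_mc,
                          anneal = anneal)$rejected
      }
      out[[cell]] <- summary_row(data.frame(family = family, m = m, n = n),
                                 k, replications)
    }
  }
  do.call(rbind, out)
}

#' Monte Carlo test versus likelihood ratio test across sample sizes
#'
#' Runs both tests on identical datasets. In `mode = "null"` the data come
#' from maximum entropy distributions with correlation drawn uniformly (Type
#' I error comparison: both tests should stay below `alpha` at every n). In
#' `mode = "mixture"` the data come from the copula mixture family with the
#' mixture parameter drawn uniformly on \[0, 1\] (power comparison: the exact
#' Monte Carlo test dominates at small n, where the chi-square approximation
#' behind the likelihood ratio test collapses).
#'
#' @param n_grid Sample sizes.
#' @param replications Datasets per sample size.
#' @param mode `"null"` or `"mixture"`.
#' @param family Mixture family for `mode = "mixture"`.
#' @param rho_range Range of the uniform correlation draw for `mode = "null"`.
#' @param rate Poisson rate.
#' @param n_mc,alpha,anneal Passed to [run_test()].
#' @param base_seed Base seed.
#' @return A data frame with one row per (test, n) cell.
#' @export
experiment_lr_comparison <- function(n_grid = c(20L, 30L, 40L),
                                     replications = 100L,
                                     mode = c("mixture", "null"),
                                     family = "M1", rho_range = c(0, 0.5),
                                     rate = 3, n_mc = 199L, alpha = 0.05,
                                     anneal = anneal_config(),
                                     base_seed = 1L) {
  mode <- match.arg(mode)
  comps <- NULL
  if (mode == "mixture") {
    base_model <- build_mixture_model(family, m = 0, rate = rate)
    comps <- list(me_pmf = base_model$me_pmf,
                  copula_pmf = base_model$copula_pmf,
                  rho2 = base_model$rho2)
  }
  out <- list()
  cell <- 0L
  for (n in n_grid) {
    cell <- cell + 1L
    k_mc <- 0L; k_lr <- 0L
    for (i in seq_len(replications)) {
      set.seed(derive_seed(base_seed, cell * 100000L + i))
      tab <- if (mode == "mixture") {
        m <- stats::runif(1)
        build_mixture_model(family, m = m, rate = rate,
                            components = comps)$pmf
      } else {
        fit_maxent(rate, rate,
                   stats::runif(1, rho_range[1], rho_range[2]))$pmf
      }
      d <- sample_pmf(tab, n)
      k_mc <- k_mc + run_test(d, "entropy_diff", alpha = alpha,
                              n_mc = n_mc, anneal = anneal)$rejected
      k_lr <- k_lr + (lr_test(d)$p_value < alpha)
    }
    out[[length(out) + 1L]] <-
      summary_row(data.frame(test = "mc_maxent", mode = mode, n = n),
                  k_mc, replications)
    out[[length(out) + 1L]] <-
      summary_row(data.frame(test = "likelihood_ratio", mode = mode, n = n),
                  k_lr, replications)
  }
  do.call(rbind, out)
}

#' Autocorrelation robustness study on gamma renewal processes
#'
#' Simulates pairs of independent gamma renewal trains, bins them into
#' counts, and applies (a) the Monte Carlo maximum entropy test to the count
#' pairs and (b) the time-rescaling Kolmogorov-Smirnov test to the pooled
#' rescaled interspike intervals of the two trains. At shape 1 the trains are
#' Poisson processes and both rejection rates sit near `alpha`; increasing
#' the shape makes the trains more regular, and both rejection rates grow —
#' the KS test faster, since it sees spike timing and not just counts.
#'
#' @param gamma_grid Gamma shape values (within \[1, 2\]).
#' @param n_grid Numbers of count pairs per dataset; the train duration is
#'   `n * bin_s`.
#' @param replications Datasets per (shape, n) cell.
#' @param rate_hz Mean firing rate (Hz).
#' @param bin_s Count bin width (seconds).
#' @param n_mc,alpha,anneal Passed to [run_test()].
#' @param base_seed Base seed.
#' @return A data frame with one row per (test, shape, n) cell.
#' @export
experiment_autocorrelation <- function(gamma_grid = c(1, 1.25, 1.5, 2),
                                       n_grid = c(50L, 100L),
                                       replications = 100L, rate_hz = 30,
                                       bin_s = 0.1, n_mc = 199L,
                                       alpha = 0.05,
                                       anneal = anneal_config(),
                                       base_seed = 1L) {
  out <- list()
  cell <- 0L
  for (g in gamma_grid) for (n in n_grid) {
    cell <- cell + 1L
    k_me <- 0L; k_ks <- 0L
    for (i in seq_len(replications)) {
      set.seed(derive_seed(base_seed, cell * 100000L + i))
      dur <- n * bin_s
      tr1 <- simulate_gamma_train(rate_hz, g, dur)
      tr2 <- simulate_gamma_train(rate_hz, g, dur)
      d <- count_pairs(bin_counts(tr1, bin_s), bin_counts(tr2, bin_s))
      k_me <- k_me + run_test(d, "entropy_diff", alpha = alpha,
                              n_mc = n_mc, anneal = anneal)$rejected
      # pooled rescaled intervals of both trains, homogeneous-rate profile
      p1 <- rescaled_uniforms(tr1)
      p2 <- rescaled_uniforms(tr2)
      k_ks <- k_ks + (stats::ks.test(c(p1, p2), "punif")$p.value < alpha)
    }
    out[[length(out) + 1L]] <-
      summary_row(data.frame(test = "mc_maxent", shape = g, n = n),
                  k_me, replications)
    out[[length(out) + 1L]] <-
      summary_row(data.frame(test = "ks_time_rescaling", shape = g, n = n),
                  k_ks, replications)
  }
  do.call(rbind, out)
}

# Uniform(0,1)-mapped rescaled interspike intervals under the homogeneous
# Poisson hypothesis with the train's own estimated rate.
rescaled_uniforms <- function(train) {
  times <- as.numeric(train)
  if (length(times) < 2L) return(numeric(0))
  rate <- length(times) / attr(train, "duration")
  1 - exp(-rate * diff(times))
}

#' Multi-pair dataset scan with false discovery rate control
#'
#' Runs the Monte Carlo maximum entropy test for every (pair, condition,
#' orientation) cell of a labelled count dataset and applies the
#' Benjamini-Hochberg correction separately within each bin size (and
#' condition) — never across bin sizes, since the adequacy of the
#' second-order model is a separate hypothesis for every bin size. With the
#' mutual-information divergence, one test per (pair, condition) pools the
#' orientations as the stimulus ensemble and the correction runs over pairs
#' only.
#'
#' @param data An [generate_fixture()]-style data frame (columns `pair`,
#'   `condition`, `orientation`, `bin_ms`, `x`, `y`).
#' @param divergence `"entropy_diff"` or `"mi_diff"`.
#' @param alpha FDR level.
#' @param n_mc,anneal Passed to [run_test()].
#' @param base_seed Base seed.
#' @return A list with `tests` (per-test table with raw p and BH decision)
#'   and `summary` (rejected fraction per bin size and condition).
#' @export
scan_counts <- function(data, divergence = "entropy_diff", alpha = 0.05,
                        n_mc = 199L, anneal = anneal_config(),
                        base_seed = 1L) {
  need <- c("pair", "condition", "orientation", "bin_ms", "x", "y")
  if (!all(need %in% names(data)))
    stop("parse error: data must have columns ",
         paste(need, collapse = ", "))
  rows <- list()
  idx <- 0L
  for (b in sort(unique(data$bin_ms))) {
    for (cond in unique(data$condition)) {
      sub <- data[data$bin_ms == b & data$condition == cond, , drop = FALSE]
      for (pr in sort(unique(sub$pair))) {
        dp <- sub[sub$pair == pr, , drop = FALSE]
        if (divergence == "mi_diff") {
          idx <- idx + 1L
          s <- count_pairs(dp$x, dp$y, stimulus = dp$orientation)
          p <- run_test(s, "mi_diff", alpha = alpha, n_mc = n_mc,
                        anneal = anneal,
                        seed = derive_seed(base_seed, idx))$p_value
          rows[[idx]] <- data.frame(bin_ms = b, condition = cond,
                                    pair = pr, orientation = NA, p = p)
        } else {
          for (ori in sort(unique(dp$orientation))) {
            idx <- idx + 1L
            dd <- dp[dp$orientation == ori, , drop = FALSE]
            p <- run_test(count_pairs(dd$x, dd$y), "entropy_diff",
                          alpha = alpha, n_mc = n_mc, anneal = anneal,
                          seed = derive_seed(base_seed, idx))$p_value
            rows[[idx]] <- data.frame(bin_ms = b, condition = cond,
                                      pair = pr, orientation = ori, p = p)
          }
        }
      }
    }
  }
  tests <- do.call(rbind, rows)
  tests$rejected <- FALSE
  for (b in unique(tests$bin_ms)) for (cond in unique(tests$condition)) {
    sel <- tests$bin_ms == b & tests$condition == cond
    tests$rejected[sel] <- bh_procedure(tests$p[sel], alpha)$rejected
  }
  summary <- do.call(rbind, lapply(unique(tests$bin_ms), function(b)
    do.call(rbind, lapply(unique(tests$condition), function(cond) {
      sel <- tests$bin_ms == b & tests$condition == cond
      data.frame(bin_ms = b, condition = cond, tests = sum(sel),
                 rejected = sum(tests$rejected[sel]),
                 fraction = mean(tests$rejected[sel]))
    }))))
  list(tests = tests, summary = summary)
}
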