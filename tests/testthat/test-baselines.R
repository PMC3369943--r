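test_that("Benjamini-Hochberg step-up matches the brute-force rule and p.adjust", {
  res <- bh_procedure(c(0.005, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(res$rejected)) # p_(4) = 0.04 <= 4 * 0.05 / 4
  expect_equal(res$threshold_index, 4L)

  expect_equal(sum(bh_procedure(rep(1, 10), 0.05)$rejected), 0)
  expect_true(bh_procedure(0.04, 0.05)$rejected) # m = 1 reduces to raw test

  # independent oracle: stats::p.adjust
  set.seed(31)
  for (i in 1:20) {
    p <- runif(25)^2
    for (alpha in c(0.01, 0.05, 0.2)) {
      expect_equal(bh_procedure(p, alpha)$rejected,
                   p.adjust(p, "BH") <= alpha)
    }
  }

  # rejection count monotone in alpha; rejection set a prefix of the order
  p <- runif(30)
  counts <- vapply(c(0.01, 0.05, 0.1, 0.3), function(a)
    sum(bh_procedure(p, a)$rejected), numeric(1))
  expect_true(all(diff(counts) >= 0))
  r <- bh_procedure(p, 0.1)
  if (r$threshold_index > 0) {
    ord <- order(p)
    expect_true(all(r$rejected[ord[seq_len(r$threshold_index)]]))
    expect_false(any(r$rejected[ord[-seq_len(r$threshold_index)]]))
  }

  expect_error(bh_procedure(c(0.5, 1.2)), "invalid parameter")
})

test_that("likelihood ratio test: validity of statistic and neuron symmetry", {
  set.seed(32)
  d <- sample_pmf(me33_rho02$pmf, 150)
  res <- lr_test(d)
  expect_gte(res$statistic, 0)
  expect_gte(res$loglik_full, res$loglik_me - 1e-8)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  # df = grid cells - 1 (saturated multinomial) - 3 (maxent parameters)
  expect_gte(res$df, (max(d$x) + 1) * (max(d$y) + 1) - 4)

  # swapping the two neurons leaves the statistic invariant (up to
  # optimizer path noise in the maxent likelihood maximization)
  swapped <- lr_test(count_pairs(d$y, d$x))
  expect_lt(abs(swapped$statistic - res$statistic), 0.5)

  expect_error(lr_test(count_pairs(1, 1)), "invalid parameter")
})

test_that("likelihood ratio test rejects strong higher-order structure at large n only", {
  mod <- build_mixture_model("M1", m = 1)
  set.seed(33)
  d <- sample_pmf(mod$pmf, 800)
  expect_lt(lr_test(d)$p_value, 0.001)
  # at small n the chi-square reference is very conservative: ~no rejections
  set.seed(34)
  d_small <- sample_pmf(mod$pmf, 30)
  expect_gt(lr_test(d_small)$p_value, 0.5)
})

test_that("Poisson Monte Carlo GOF holds its level and detects overdispersion", {
  set.seed(34)
  # level under H0 (42 counts, as in a typical repetition budget)
  ps <- replicate(30, poisson_gof_mc(rpois(42, 3), n_mc = 99,
                                     anneal = anneal_config(steps = 15)))
  expect_lte(mean(ps < 0.05), 0.15) # binomial slack around <= 0.05

  # degenerate all-zero sample
  expect_equal(poisson_gof_mc(rep(0, 20)), 1)

  # strong overdispersion: mixture of Poisson(1) and Poisson(10)
  rej <- replicate(15, {
    counts <- c(rpois(50, 1), rpois(50, 10))
    poisson_gof_mc(counts, n_mc = 99,
                   anneal = anneal_config(steps = 15)) < 0.05
  })
  expect_gt(mean(rej), 0.5)
})

test_that("time rescaling KS test: level for Poisson, power against regular trains", {
  set.seed(35)
  # homogeneous Poisson process with known rate: p approximately uniform
  ps <- replicate(40, {
    tr <- simulate_gamma_train(30, 1, 10)
    time_rescaling_ks(tr, rate_per_bin = 30, bin_s = 10)
  })
  expect_lte(mean(ps < 0.05), 0.175)
  expect_gt(mean(ps), 0.3) # not degenerate towards 0

  # gamma shape 2: substantially higher rejection than shape 1
  rej2 <- mean(replicate(20, {
    tr <- simulate_gamma_train(30, 2, 10)
    time_rescaling_ks(tr, rate_per_bin = 30, bin_s = 10) < 0.05
  }))
  expect_gt(rej2, 0.5)

  # deterministic evenly spaced spikes: overwhelming rejection
  tr_det <- spike_train(seq(1 / 30, 10, by = 1 / 30) - 1e-9, 10)
  # identical intervals tie in the KS statistic; the warning is expected here
  p_det <- suppressWarnings(
    time_rescaling_ks(tr_det, rate_per_bin = 30, bin_s = 10))
  expect_lt(p_det, 1e-4)

  expect_error(time_rescaling_ks(spike_train(0.5, 1)), "insufficient data")
})
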