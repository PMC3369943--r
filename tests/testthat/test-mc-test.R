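test_that("rank p-value formula: extremes and the lattice", {
  mc <- 1:99 / 100
  expect_equal(mc_p_value(2, mc, seed = 1), 1 / 100)
  expect_equal(mc_p_value(0, mc, seed = 1), 1)
  expect_error(mc_p_value(1, numeric(0)), "invalid parameter")
  expect_error(mc_p_value(NaN, mc), "invalid parameter")

  # always on the lattice {1/(N+1), ..., 1}
  set.seed(2)
  for (i in 1:50) {
    p <- mc_p_value(rnorm(1), rnorm(19))
    expect_lt(abs(p * 20 - round(p * 20)), 1e-9)
  }
})

test_that("tie breaking makes the p-value exchangeable under full ties", {
  # all N+1 statistics identical: p should be uniform on {1/20, ..., 1}
  # with mean (N+2)/(2(N+1)) = 0.525 (exchangeability brute-force)
  set.seed(3)
  ps <- replicate(1e4, mc_p_value(1, rep(1, 19)))
  expect_equal(mean(ps), 0.525, tolerance = 0.01)
  expect_true(all(abs(ps * 20 - round(ps * 20)) < 1e-9))
  expect_gt(min(ps), 0)
  expect_lte(max(ps), 1)
})

test_that("evaluate_p detects an impossible dataset and respects granularity", {
  d <- count_pairs(rep(15, 50), rep(0, 50))
  p <- evaluate_p(d, list(rate_x = 3, rate_y = 3, rho = 0),
                  n_mc = 99, seed = 4)
  expect_equal(p, 1 / 100)

  d2 <- sample_pmf(me33_rho02$pmf, 60, seed = 5)
  p2 <- evaluate_p(d2, list(rate_x = 3, rate_y = 3, rho = 0.2),
                   n_mc = 199, seed = 6)
  expect_lt(abs(p2 * 200 - round(p2 * 200)), 1e-9)
  expect_error(evaluate_p(d2, list(rate_x = 3, rate_y = 3, rho = 0.2),
                          n_mc = 5), "invalid parameter")
})

test_that("nuisance optimization never returns less than the initial p-value", {
  set.seed(7)
  d <- sample_pmf(me33_rho02$pmf, 80)
  res <- optimize_nuisance(d, "entropy_diff", n_mc = 99,
                           anneal = anneal_config(steps = 15))
  expect_gte(res$p_value, res$trace$p[1])
  expect_equal(res$p_value, max(res$trace$p))
  expect_lt(abs(res$p_value * 100 - round(res$p_value * 100)), 1e-9)
})

test_that("run_test is deterministic given a seed and handles label policy", {
  d <- sample_pmf(me33_rho02$pmf, 40, seed = 8)
  r1 <- run_test(d, n_mc = 99, anneal = fast_anneal, seed = 9)
  r2 <- run_test(d, n_mc = 99, anneal = fast_anneal, seed = 9)
  expect_identical(r1, r2)

  labelled <- count_pairs(d$x, d$y, stimulus = rep(c("a", "b"), 20))
  expect_message(run_test(labelled, "entropy_diff", n_mc = 99,
                          anneal = fast_anneal, seed = 9),
                 "ignored")
  expect_error(run_test(d, "mi_diff", n_mc = 99, anneal = fast_anneal),
               "labeling error")
  expect_error(run_test(d, alpha = 0), "invalid parameter")
})

test_that("decision uses strict inequality at the significance level", {
  d <- count_pairs(rep(15, 50), rep(0, 50))
  res <- run_test(d, n_mc = 19, anneal = fast_anneal, seed = 10,
                  alpha = 0.05)
  expect_equal(res$p_value, 1 / 20)
  expect_false(res$rejected) # p == alpha is not a rejection
  res2 <- run_test(d, n_mc = 99, anneal = fast_anneal, seed = 10,
                   alpha = 0.05)
  expect_true(res2$rejected) # 1/100 < 0.05
})

test_that("mutual-information variant runs with per-stimulus nuisance triples", {
  me2 <- fit_maxent(2, 2, 0)$pmf
  me4 <- fit_maxent(4, 4, 0)$pmf
  set.seed(11)
  d1 <- sample_pmf(me2, 30); d2 <- sample_pmf(me4, 30)
  d <- count_pairs(c(d1$x, d2$x), c(d1$y, d2$y),
                   stimulus = rep(c("a", "b"), each = 30))
  res <- run_test(d, "mi_diff", n_mc = 99, anneal = fast_anneal, seed = 12)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_named(res$best_params, c("a", "b"))
  expect_equal(res$divergence, "mi_diff")
})

test_that("test result serializes to JSON with provenance fields", {
  d <- sample_pmf(me33_rho02$pmf, 30, seed = 13)
  res <- run_test(d, n_mc = 99, anneal = fast_anneal, seed = 14)
  js <- jsonlite::fromJSON(test_result_to_json(res))
  expect_equal(js$p_value, res$p_value)
  expect_equal(js$divergence, "entropy_diff")
  expect_equal(length(js$mc_divergences), 99)
  expect_equal(js$anneal$steps, 10)
})
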