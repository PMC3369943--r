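test_that("support truncation matches direct CDF summation and is monotone in rate", {
  # independent oracle: cumulative summation of the Poisson pmf
  cdf_bound <- function(rate, eps) {
    cum <- cumsum(dpois(0:200, rate))
    which(cum >= 1 - eps)[1] - 1L
  }
  s <- truncate_support(poisson_marginal(3), poisson_marginal(3), 1e-10)
  expect_equal(s$max_x, cdf_bound(3, 1e-10))
  expect_equal(s$max_y, s$max_x)

  s5 <- truncate_support(poisson_marginal(5), poisson_marginal(3), 1e-10)
  expect_gte(s5$max_x, s$max_x)

  # near-zero rate: floor of 1
  s0 <- truncate_support(poisson_marginal(1e-8), poisson_marginal(1e-8), 1e-5)
  expect_equal(s0$max_x, 1L)

  expect_error(poisson_marginal(Inf), "invalid parameter")
  expect_error(truncate_support(3, 3, 1e-3), "invalid parameter")
})

test_that("bivariate pmf validates normalization and nonnegativity", {
  expect_error(bivariate_pmf(matrix(c(0.5, 0.5, 0.1, 0), 2, 2)),
               "sum to 1")
  expect_error(bivariate_pmf(matrix(c(1.2, -0.2, 0, 0), 2, 2)),
               "nonnegative")
  p <- bivariate_pmf(matrix(c(3, 1, 1, 3), 2, 2), normalize = TRUE)
  expect_equal(sum(p), 1, tolerance = 1e-14)
})

test_that("entropy: uniform, point mass, and product additivity", {
  expect_equal(entropy(bivariate_pmf(matrix(0.25, 2, 2))), 2)
  expect_equal(entropy(bivariate_pmf(matrix(c(1, 0, 0, 0), 2, 2))), 0)

  # product table entropy = sum of marginal entropies (direct summation)
  px <- dpois(0:19, 3) / ppois(19, 3)
  h1 <- -sum(px[px > 0] * log2(px[px > 0]))
  prod_tab <- bivariate_pmf(outer(px, px), normalize = TRUE)
  expect_equal(entropy(prod_tab), 2 * h1, tolerance = 1e-10)
})

test_that("pearson correlation: product, comonotone, degenerate cases", {
  px <- dpois(0:10, 2) / ppois(10, 2)
  expect_equal(pearson_correlation(bivariate_pmf(outer(px, px),
                                                 normalize = TRUE)),
               0, tolerance = 1e-12)
  diag2 <- bivariate_pmf(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(pearson_correlation(diag2), 1)
  degenerate <- bivariate_pmf(matrix(c(0.5, 0.5, 0, 0), 2, 2))
  expect_error(pearson_correlation(degenerate), "degenerate marginal")
})

test_that("sampling is reproducible, exact for point mass, unbiased for product", {
  pm <- bivariate_pmf(matrix(c(0, 0, 0, 1), 2, 2))
  s <- sample_pmf(pm, 5, seed = 1)
  expect_equal(s$x, rep(1L, 5))
  expect_equal(s$y, rep(1L, 5))

  s1 <- sample_pmf(me33_rho02$pmf, 50, seed = 42)
  s2 <- sample_pmf(me33_rho02$pmf, 50, seed = 42)
  expect_identical(s1, s2)

  px <- dpois(0:19, 3) / ppois(19, 3)
  prod_tab <- bivariate_pmf(outer(px, px), normalize = TRUE)
  big <- sample_pmf(prod_tab, 1e5, seed = 7)
  se <- sqrt(3 / 1e5) # Poisson variance ~ rate
  expect_lt(abs(mean(big$x) - 3), 3 * se)
  expect_lt(abs(mean(big$y) - 3), 3 * se)

  expect_error(sample_pmf(pm, 0), "invalid parameter")
})

test_that("empirical pmf counts frequencies and expands the support", {
  s <- count_pairs(c(0, 0, 1, 1), c(0, 0, 2, 2))
  e <- empirical_pmf(s, small_support(1))
  expect_equal(e[1, 1], 0.5)
  expect_equal(e[2, 3], 0.5)
  expect_equal(sum(e), 1)
  # frequencies times n are integers
  expect_true(all(abs(e * 4 - round(e * 4)) < 1e-12))

  e1 <- empirical_pmf(count_pairs(3, 5), small_support(1))
  expect_equal(e1[4, 6], 1)
})

test_that("count pairs validate inputs and labels", {
  expect_error(count_pairs(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(count_pairs(-1, 0), "nonnegative")
  expect_error(count_pairs(c(1, 2), c(1, 2), stimulus = "a"),
               "labeling error")
  d <- count_pairs(c(1, 2), c(0, 1), stimulus = c("a", "b"))
  expect_equal(d$stimulus, c("a", "b"))
})
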