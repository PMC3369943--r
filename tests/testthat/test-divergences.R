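test_that("entropy difference: identity, extremes, and oracle agreement", {
  u <- bivariate_pmf(matrix(0.25, 2, 2))
  expect_equal(entropy_difference(u, u), 0)
  pm <- bivariate_pmf(matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(entropy_difference(u, pm), 2)

  set.seed(11)
  s <- sample_pmf(me33_rho02$pmf, 200)
  emp <- empirical_pmf(s, pmf_support_of(me33_rho02$pmf))
  # independent direct-summation oracle for both entropies
  hs <- function(p) { p <- as.numeric(p); p <- p[p > 0]; -sum(p * log2(p)) }
  expect_equal(entropy_difference(emp, me33_rho02$pmf),
               abs(hs(emp) - hs(me33_rho02$pmf)), tolerance = 1e-12)
})

test_that("additive bias cancellation holds by construction", {
  # shifting both entropy estimates by any constant leaves the statistic
  # unchanged: |(H1+c) - (H2+c)| == |H1 - H2|
  h1 <- 3.1; h2 <- 2.7
  for (c_shift in c(-1, 0, 0.5)) {
    expect_equal(abs((h1 + c_shift) - (h2 + c_shift)), abs(h1 - h2))
  }
})

test_that("mutual information: identical conditionals, disjoint supports, brute force", {
  u <- bivariate_pmf(matrix(0.25, 2, 2))
  expect_equal(mutual_information(list(u, u, u)), 0)

  a <- bivariate_pmf(matrix(c(1, 0, 0, 0), 2, 2))
  b <- bivariate_pmf(matrix(c(0, 0, 0, 1), 2, 2))
  expect_equal(mutual_information(list(a, b)), 1)

  # 8 stimuli with maxent conditionals: brute-force double sum oracle
  set.seed(5)
  rates <- runif(8, 1, 5)
  conds <- lapply(rates, function(r) fit_maxent(r, r, 0.1)$pmf)
  nx <- max(vapply(conds, nrow, 1L)); ny <- max(vapply(conds, ncol, 1L))
  padded <- lapply(conds, function(p) {
    out <- matrix(0, nx, ny); out[1:nrow(p), 1:ncol(p)] <- p; out
  })
  brute <- 0
  mix <- Reduce(`+`, padded) / 8
  for (s in 1:8) for (i in 1:nx) for (j in 1:ny) {
    if (padded[[s]][i, j] > 0)
      brute <- brute + (1 / 8) * padded[[s]][i, j] *
        log2(padded[[s]][i, j] / mix[i, j])
  }
  expect_equal(mutual_information(conds), brute, tolerance = 1e-10)

  # flat-prior bound
  expect_lte(mutual_information(conds), log2(8))
})

test_that("mutual information difference: identity, reduction, and sensitivity", {
  m1 <- fit_maxent(2, 2, 0)$pmf
  m2 <- fit_maxent(4, 4, 0)$pmf
  refs <- stimulus_ensemble(list(a = m1, b = m2))

  # empirical conditionals exactly equal to references -> 0
  # (build a sample whose empirical tables coincide with tiny tables)
  ta <- bivariate_pmf(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  tb <- bivariate_pmf(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  d <- count_pairs(c(0, 1, 1, 0), c(0, 1, 0, 1),
                   stimulus = c("a", "a", "b", "b"))
  refs2 <- stimulus_ensemble(list(a = ta, b = tb))
  expect_equal(mi_difference(d, refs2), 0, tolerance = 1e-12)

  # identical reference tables for all stimuli: statistic reduces to the
  # empirical mutual information
  refs3 <- stimulus_ensemble(list(a = m1, b = m1))
  emp_a <- empirical_pmf(count_pairs(c(0, 1), c(0, 1)), small_support(1))
  emp_b <- empirical_pmf(count_pairs(c(1, 0), c(0, 1)), small_support(1))
  d3 <- count_pairs(c(0, 1, 1, 0), c(0, 1, 0, 1),
                    stimulus = c("a", "a", "b", "b"))
  expect_equal(mi_difference(d3, refs3),
               mutual_information(list(emp_a, emp_b)), tolerance = 1e-12)

  expect_error(mi_difference(count_pairs(1, 1), refs), "labeling error")
  expect_error(
    mi_difference(count_pairs(c(1, 1), c(1, 1), stimulus = c("a", "zzz")),
                  refs),
    "labeling error")
})

test_that("mixture-generated data raise the MI statistic against matched maxent refs", {
  # two stimuli: one maxent, one strongly higher-order (M1 copula side);
  # the reference ensemble uses matched-correlation maxent tables, so the
  # statistic should be positive in expectation
  mod <- build_mixture_model("M1", m = 1, rate = 3)
  me <- fit_maxent(3, 3, 0)$pmf
  refs <- stimulus_ensemble(list(s1 = me, s2 = me))
  set.seed(9)
  stats <- replicate(20, {
    d1 <- sample_pmf(me, 60)
    d2 <- sample_pmf(mod$pmf, 60)
    d <- count_pairs(c(d1$x, d2$x), c(d1$y, d2$y),
                     stimulus = rep(c("s1", "s2"), each = 60))
    mi_difference(d, refs)
  })
  expect_gt(mean(stats), 0)
})
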