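test_that("Gaussian copula boundary behaviour and independence", {
  u <- c(0.1, 0.4, 0.7)
  expect_equal(gaussian_copula_cdf(0, u, 1), u)
  expect_equal(gaussian_copula_cdf(0.6, 1, u), u)
  expect_equal(gaussian_copula_cdf(0.6, u, 0), rep(0, 3))
  expect_equal(gaussian_copula_cdf(0, 0.3, 0.7), 0.21, tolerance = 1e-9)
  # closed form at the median: C(1/2, 1/2) = 1/4 + asin(rho) / (2 pi)
  expect_equal(gaussian_copula_cdf(0.5, 0.5, 0.5),
               0.25 + asin(0.5) / (2 * pi), tolerance = 1e-8)
  expect_error(gaussian_copula_cdf(0.5, 1.2, 0.5), "invalid parameter")
  expect_error(gaussian_copula_cdf(1, 0.5, 0.5), "invalid parameter")
})

test_that("copula pmf reproduces marginals and the independence product", {
  sup <- truncate_support(3, 3)
  indep <- copula_pmf(0, 3, 3, sup)
  px <- dpois(0:sup$max_x, 3) / ppois(sup$max_x, 3)
  expect_lt(max(abs(unclass(indep) - outer(px, px))), 1e-9)

  for (rho_c in c(-0.7, 0.3, 0.9)) {
    tab <- copula_pmf(rho_c, 3, 3, sup)
    expect_lt(max(abs(marginal_pmf(tab, 1) - px)), 1e-8)
    expect_lt(max(abs(marginal_pmf(tab, 2) - px)), 1e-8)
    expect_gte(min(tab), 0)
  }
})

test_that("strong-copula table correlation matches a large sampling estimate", {
  tab <- copula_pmf(0.9, 3, 3)
  rho_exact <- pearson_correlation(tab)
  s <- sample_pmf(tab, 1e6, seed = 21)
  rho_hat <- cor(s$x, s$y)
  se <- (1 - rho_exact^2) / sqrt(1e6)
  expect_lt(abs(rho_hat - rho_exact), 3 * se)
})

test_that("calibration of the second copula parameter hits the target", {
  r2 <- calibrate_rho2(0.9, 0.5, 0, 3, 3)
  expect_lt(r2, 0) # countermonotone component needed to cancel rho1 = 0.9
  tab <- copula_pmf(mixture_copula(0.9, r2, 0.5), 3, 3)
  expect_equal(pearson_correlation(tab), 0, tolerance = 1e-4)

  # fixed point: target equal to the correlation at rho2 = rho1
  tab_eq <- copula_pmf(mixture_copula(0.4, 0.4, 0.5), 3, 3)
  r_eq <- calibrate_rho2(0.4, 0.5, pearson_correlation(tab_eq), 3, 3)
  expect_equal(r_eq, 0.4, tolerance = 1e-4)

  expect_error(calibrate_rho2(0.9, 0.5, 0.999, 3, 3),
               "calibration infeasible")
})

test_that("mixture families keep marginals and correlation fixed across m", {
  for (family in c("M1", "M2")) {
    target <- if (family == "M1") 0 else 0.2
    base <- build_mixture_model(family, m = 0)
    comps <- list(me_pmf = base$me_pmf, copula_pmf = base$copula_pmf,
                  rho2 = base$rho2)
    px <- dpois(0:(nrow(base$pmf) - 1), 3) / ppois(nrow(base$pmf) - 1, 3)
    for (m in c(0, 0.25, 0.5, 0.75, 1)) {
      mod <- build_mixture_model(family, m = m, components = comps)
      expect_equal(pearson_correlation(mod$pmf), target, tolerance = 0.005)
      expect_lt(max(abs(marginal_pmf(mod$pmf, 1) - px)), 1e-8)
      expect_lt(max(abs(marginal_pmf(mod$pmf, 2) - px)), 1e-8)
    }
    # m = 0 is exactly the maximum entropy component
    expect_equal(unclass(build_mixture_model(family, m = 0,
                                             components = comps)$pmf),
                 unclass(base$me_pmf), tolerance = 1e-12)
  }
})

test_that("pure copula component of M1 shows the cross-shaped mass excess", {
  mod <- build_mixture_model("M1", m = 1)
  tab <- unclass(mod$pmf)
  px <- marginal_pmf(mod$pmf, 1); py <- marginal_pmf(mod$pmf, 2)
  indep <- outer(px, py)
  K <- nrow(tab)
  main_diag <- sum(diag(tab))
  anti_diag <- sum(tab[cbind(1:K, K:1)])
  expect_gt(main_diag + anti_diag,
            sum(diag(indep)) + sum(indep[cbind(1:K, K:1)]))
})

test_that("entropy gap to the maxent reference grows with the mixture parameter", {
  base <- build_mixture_model("M1", m = 0)
  comps <- list(me_pmf = base$me_pmf, copula_pmf = base$copula_pmf,
                rho2 = base$rho2)
  h_me <- entropy(base$me_pmf)
  gaps <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(m)
    h_me - entropy(build_mixture_model("M1", m = m,
                                       components = comps)$pmf),
    numeric(1))
  expect_true(all(diff(gaps) > -1e-9))
  expect_gte(min(gaps), 0)
  expect_gt(gaps[5], gaps[1])
})
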