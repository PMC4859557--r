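test_that("telegraph-like pmf matches independent positive-series and quadrature oracles", {
  grid <- expand.grid(lam = c(0.1, 0.3, 1, 3), mu = c(5, 10, 20))
  for (i in seq_len(nrow(grid))) {
    tel <- telegraph_pmf(grid$lam[i], grid$mu[i])
    oracle <- telegraph_series(grid$lam[i], grid$lam[i], grid$mu[i], tel$M)
    expect_lt(tv_dist(tel, oracle), 1e-10)
  }
  # asymmetric case used by the lumpability check
  tel2 <- telegraph_pmf(1.2, 9, lam_off = 0.5)
  expect_lt(tv_dist(tel2, telegraph_series(1.2, 0.5, 9, tel2$M)), 1e-10)
  # quadrature route where the beta density is endpoint-regular
  tel3 <- telegraph_pmf(2, 8, lam_off = 1.5)
  expect_lt(tv_dist(tel3, telegraph_quadrature(2, 1.5, 8, tel3$M)), 1e-8)
})

test_that("telegraph-like pmf has the right limits", {
  expect_gt(telegraph_pmf(0.5, 1e-8)$probs[1], 1 - 1e-6)
  # fast switching approaches Poisson(mu/2) at rate O(mu/lam)
  fast <- telegraph_pmf(2000, 10)
  expect_lt(tv_dist(fast, stats::dpois(0:fast$M, 5)), 1e-3)
})

test_that("the all-equal-rates promoter is exactly lumpable to a telegraph gene", {
  for (lam in c(0.3, 1)) {
    mu <- 10
    gp <- build_generator(all_equal_rates(lam), mu, mu)
    rec <- reconstruct_distribution(solve_moments(gp$A, gp$Lambda))
    expect_lt(tv_dist(rec, telegraph_pmf(lam, mu, M = rec$M)), 1e-10)
  }
  # general lumpability: equal vertical and equal horizontal rates collapse
  # the square cycle to a two-state chain with on-rate lam14, off-rate lam41
  rs <- rate_list(1.2, 0.7, 0.4, 1.2, 0.5, 0.7, 0.4, 0.5)
  gp <- build_generator(rs, 9, 9)
  rec <- reconstruct_distribution(solve_moments(gp$A, gp$Lambda))
  expect_lt(tv_dist(rec, telegraph_pmf(1.2, 9, M = rec$M, lam_off = 0.5)),
            1e-10)
})

test_that("mixture pmf collapses to Poisson when gamma = alpha", {
  mx <- mixture_pmf(1, list(c(1, 2, 3)), c(1, 2, 3), mu = 5, M = 40)
  expect_lt(sup_dist(mx, stats::dpois(0:40, 5)), 1e-12)
  expect_error(mixture_pmf(1, list(c(1, 2)), c(1, 2, 3), mu = 5),
               "length 3")
  expect_error(mixture_pmf(c(0.6, 0.6), list(c(1, 2, 3), c(1, 2, 3)),
                           c(1, 2, 3), mu = 5), "sum to 1")
})

test_that("mixture parameterized from the generator spectrum reproduces the solver", {
  # all-equal-rates generator: nonzero eigenvalues -2l, -2l, -4l; choosing
  # gamma = (l, 2l, 4l) cancels two Pochhammer pairs and must reproduce the
  # telegraph-form solution, so one mixture component suffices
  lam <- 0.5
  mu <- 8
  gp <- build_generator(all_equal_rates(lam), mu, mu)
  alphas <- sort(-Re(eigen(gp$A)$values))[-1]
  expect_equal(alphas, c(2 * lam, 2 * lam, 4 * lam), tolerance = 1e-10)
  rec <- reconstruct_distribution(solve_moments(gp$A, gp$Lambda))
  mx <- mixture_pmf(c(1, 0), list(c(lam, 2 * lam, 4 * lam), alphas), alphas,
                    mu, M = rec$M)
  expect_lt(tv_dist(mx, rec), 1e-10)
  # degenerate weights reduce to the single component
  mx1 <- mixture_pmf(1, list(c(lam, 2 * lam, 4 * lam)), alphas, mu, M = rec$M)
  expect_identical(mx$probs, mx1$probs)
})

test_that("2F2 pmf collapses to Poisson and its noise formula is self-consistent", {
  p <- two_f_two_pmf(6, c(1.1, 2.3), c(1.1, 2.3), M = 50)
  expect_lt(sup_dist(p, stats::dpois(0:50, 6)), 1e-12)
  expect_equal(two_f_two_noise(6, c(1.1, 2.3), c(1.1, 2.3)), 1 / 6,
               tolerance = 1e-12)
  # consistent reading reproduces the distribution's own variance/mean^2;
  # the literal typeset grouping does not
  for (par in list(list(mt = 8, a = c(0.9, 2.2), b = c(1.5, 3.1)),
                   list(mt = 12, a = c(1.4, 1.9), b = c(2.5, 4.0)))) {
    pmf <- two_f_two_pmf(par$mt, par$a, par$b, M = 120)
    eta_pmf <- pmf_noise(pmf)
    expect_equal(two_f_two_noise(par$mt, par$a, par$b), eta_pmf,
                 tolerance = 1e-8)
    expect_gt(abs(two_f_two_noise(par$mt, par$a, par$b, "literal") - eta_pmf),
              1e-3)
  }
})

test_that("2F2 parameters are recovered exactly from 2F2 moments", {
  p <- two_f_two_pmf(8, c(0.9, 2.2), c(1.5, 3.1), M = 100)
  fit <- fit_two_f_two(empirical_binomial_moments(p, 6))
  expect_equal(unname(fit$mu_tilde), 8, tolerance = 1e-8)
  expect_equal(unname(fit$a_pair), c(0.9, 2.2), tolerance = 1e-6)
  expect_equal(unname(fit$b_pair), c(1.5, 3.1), tolerance = 1e-6)
})

test_that("moment-matched 2F2 captures the special side-by-side configuration", {
  # blue-opening rates scaled by k, all other rates lam: the matched 2F2
  # reproduces mean and noise exactly; the full distribution agrees only
  # approximately (the generator has three distinct nonzero eigenvalues, so
  # the closed form is not exact away from k = 1)
  lam <- 0.8
  k <- 2.5
  mu <- 12
  rs <- rate_list(lam, lam, lam, k * lam, lam, k * lam, lam, lam)
  gp <- build_generator(rs, mu, mu)
  mom <- solve_moments(gp$A, gp$Lambda)
  st <- summary_stats(mom)
  fit <- fit_two_f_two(mom)
  expect_equal(two_f_two_noise(fit$mu_tilde, fit$a_pair, fit$b_pair), st$eta,
               tolerance = 1e-10)
  pmf2 <- two_f_two_pmf(fit$mu_tilde, fit$a_pair, fit$b_pair)
  expect_equal(pmf_mean(pmf2), st$mean, tolerance = 1e-8)
  rec <- reconstruct_distribution(mom)
  expect_lt(tv_dist(pmf2, rec), 1e-3)
  # matched moments agree exactly up to the fitted order
  B2 <- empirical_binomial_moments(pmf2, 5)
  expect_equal(unname(mom$totals[1:6]), B2, tolerance = 1e-7)
})

test_that("analytic pmfs are normalized and nonnegative", {
  pmfs <- list(telegraph_pmf(0.3, 10), telegraph_pmf(3, 20),
               two_f_two_pmf(10, c(0.7, 1.8), c(1.2, 2.9)),
               mixture_pmf(c(0.4, 0.6),
                           list(c(0.5, 1, 2), c(0.8, 1.5, 2.5)),
                           c(1, 2, 3), mu = 7, M = 60))
  for (p in pmfs) {
    expect_equal(sum(p$probs), 1, tolerance = 1e-10)
    expect_true(all(p$probs >= 0))
  }
})
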