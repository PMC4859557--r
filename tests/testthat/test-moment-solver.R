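test_that("stationary law is uniform for the symmetric cycle and errors on reducible chains", {
  gp <- build_generator(all_equal_rates(0.8), 10, 10)
  expect_equal(unname(stationary_probs(gp$A)), rep(0.25, 4), tolerance = 1e-12)
  # cutting every cross edge leaves two disconnected pairs
  A_red <- build_generator(rate_list(1, 0, 0, 0, 0, 0, 0, 1), 10, 10)$A
  expect_error(stationary_probs(A_red), "reducible")
  expect_error(solve_moments(A_red, rep(1, 4)), "reducible")
})

test_that("unconditioned transcription gives exact Poisson binomial moments", {
  # harness generalization: Lambda = mu * I makes the copy number Poisson(mu)
  # regardless of the promoter dynamics
  for (mu in c(3, 10)) {
    gp <- build_generator(rate_list(1.3, 0.7, 0.4, 2.2, 0.5, 1.1, 0.9, 0.6),
                          mu, mu)
    mom <- solve_moments(gp$A, rep(mu, 4), K = 30)
    k <- 0:30
    expect_equal(unname(mom$totals), mu^k / factorial(k),
                 tolerance = 1e-12)
    pmf <- reconstruct_distribution(mom, M = ceiling(mu + 12 * sqrt(mu)))
    expect_lt(sup_dist(pmf, stats::dpois(0:pmf$M, mu)), 1e-12)
  }
})

test_that("symmetric switching halves the transcriptional output", {
  mu <- 10
  gp <- build_generator(all_equal_rates(0.5), mu, mu)
  mom <- solve_moments(gp$A, gp$Lambda)
  expect_equal(mom$totals[["B1"]], mu / 2, tolerance = 1e-12)
})

test_that("solver moments equal binomial moments of the FSP distribution", {
  cfgs <- random_rate_configs(4, seed = 21)
  for (cc in cfgs) {
    gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
    mom <- solve_moments(gp$A, gp$Lambda, K = 6)
    fsp <- fsp_steady_state(gp$A, gp$Lambda)
    Bk_fsp <- empirical_binomial_moments(fsp, 6)
    expect_equal(unname(mom$totals[1:7]), Bk_fsp, tolerance = 1e-9)
  }
})

test_that("reconstruction agrees with FSP to high accuracy", {
  cfgs <- random_rate_configs(4, seed = 31)
  for (cc in cfgs) {
    gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
    mom <- solve_moments(gp$A, gp$Lambda)
    rec <- reconstruct_distribution(mom)
    fsp <- fsp_steady_state(gp$A, gp$Lambda)
    expect_lt(sup_dist(rec, fsp), 1e-10)
    expect_equal(sum(rec$probs), 1, tolerance = 1e-10)
    expect_true(all(rec$probs >= 0))
    expect_lt(rec$probs[rec$M + 1], 1e-10)
  }
})

test_that("zero transcription concentrates all mass at zero copies", {
  gp <- build_generator(all_equal_rates(0.5), 0, 0)
  fsp <- fsp_steady_state(gp$A, gp$Lambda, M = 3)
  expect_equal(fsp$probs[1], 1, tolerance = 1e-12)
  mom <- solve_moments(gp$A, gp$Lambda, K = 5)
  expect_equal(unname(mom$totals[-1]), rep(0, 5), tolerance = 1e-14)
})

test_that("relabeling promoter states leaves the mRNA distribution invariant", {
  cc <- random_rate_configs(1, seed = 41)[[1]]
  gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
  base <- reconstruct_distribution(solve_moments(gp$A, gp$Lambda))
  for (perm in list(c(2, 1, 4, 3), c(4, 3, 2, 1), c(3, 1, 4, 2))) {
    P <- diag(4)[perm, ]
    A2 <- P %*% gp$A %*% t(P)
    L2 <- P %*% gp$Lambda %*% t(P)
    expect_lt(sup_dist(reconstruct_distribution(solve_moments(A2, L2)), base),
              1e-12)
  }
})

test_that("degradation rescaling matches the delta = 1 solution in rescaled time", {
  # mean scales as 1/delta; the stationary law depends only on rates/delta
  cc <- random_rate_configs(1, seed = 51)[[1]]
  gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
  delta <- 2.5
  mom_d <- solve_moments(gp$A, gp$Lambda, delta = delta)
  gp_scaled <- build_generator(lapply(cc$rates, `/`, delta),
                               cc$mu1 / delta, cc$mu2 / delta)
  mom_1 <- solve_moments(gp_scaled$A, gp_scaled$Lambda, delta = 1)
  expect_equal(unname(mom_d$totals[1:6]), unname(mom_1$totals[1:6]),
               tolerance = 1e-12)
})

test_that("doubling the truncation order does not move the distribution", {
  cc <- random_rate_configs(1, seed = 61)[[1]]
  gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
  mom <- solve_moments(gp$A, gp$Lambda)
  rec1 <- reconstruct_distribution(mom, M = 40)
  mom2 <- solve_moments(gp$A, gp$Lambda, K = 2 * mom$K)
  rec2 <- reconstruct_distribution(mom2, M = 40)
  expect_lt(sup_dist(rec1, rec2), 1e-10)
})

test_that("summary statistics match the reconstructed distribution and Poisson identities", {
  # Poisson(mu): eta = 1/mu, skewness = mu^(-1/2), kurtosis = 3 + 1/mu
  mu <- 7
  gp <- build_generator(all_equal_rates(1), mu, mu)
  momp <- solve_moments(gp$A, rep(mu, 4), K = 10)
  st <- summary_stats(momp)
  expect_equal(st$mean, mu, tolerance = 1e-12)
  expect_equal(st$eta, 1 / mu, tolerance = 1e-10)
  expect_equal(st$fano, 1, tolerance = 1e-10)
  expect_equal(st$skewness, mu^-0.5, tolerance = 1e-8)
  expect_equal(st$kurtosis, 3 + 1 / mu, tolerance = 1e-8)
  # internal consistency against the pmf for a switching config
  cc <- random_rate_configs(1, seed = 71)[[1]]
  gp2 <- build_generator(cc$rates, cc$mu1, cc$mu2)
  mom2 <- solve_moments(gp2$A, gp2$Lambda)
  st2 <- summary_stats(mom2)
  rec2 <- reconstruct_distribution(mom2)
  expect_equal(st2$eta, pmf_noise(rec2), tolerance = 1e-8)
  expect_equal(st2$mean, pmf_mean(rec2), tolerance = 1e-8)
  # mixture-of-Poissons noise floor
  expect_gte(st2$eta, 1 / st2$mean - 1e-12)
})

test_that("binomial moments are nonnegative and eventually decreasing", {
  cfgs <- random_rate_configs(3, seed = 81)
  for (cc in cfgs) {
    gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
    mom <- solve_moments(gp$A, gp$Lambda)
    B <- unname(mom$totals)
    expect_true(all(B > -1e-14))
    kmax <- which.max(B)
    expect_true(all(diff(B[kmax:length(B)]) <= 1e-14))
    expect_lt(B[length(B)], 1e-8)
  }
})
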