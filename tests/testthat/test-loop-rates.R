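test_that("looping rate law matches its closed form and rejects bad input", {
  lp <- loop_params()
  # at d = 1 the log term vanishes: rate = exp(z + w - u)
  expect_equal(looping_rate(1), exp(19.9 + 0.0014 - 140.6))
  expect_equal(looping_rate(2, loop_params(kRon = 3)),
               3 * exp(-140.6 / 2 - 2.52 * log(2) + 0.0014 * 2 + 19.9))
  d <- exp(seq(log(0.5), log(1e5), length.out = 200))
  expect_true(all(is.finite(looping_rate(d))) && all(looping_rate(d) > 0))
  expect_error(looping_rate(0), "d must be")
  expect_error(looping_rate(-5), "d must be")
})

test_that("looping rate has the stationary points of w d^2 - v d + u", {
  lp <- loop_params()
  roots <- sort(Re(polyroot(c(lp$u, -lp$v, lp$w))))
  # brute-force maximization on a dense grid over (0, 200)
  grid <- seq(0.5, 200, by = 0.01)
  d_hat <- grid[which.max(looping_rate(grid))]
  expect_lt(abs(d_hat - roots[1]), 0.02)
  # strictly decreasing between the two stationary points
  mid <- seq(roots[1] + 1, roots[2] - 1, length.out = 500)
  expect_true(all(diff(looping_rate(mid)) < 0))
  # and the second stationary point is a minimum (increasing beyond it)
  expect_true(all(diff(looping_rate(seq(roots[2] + 1, roots[2] + 500))) > 0))
})

test_that("interaction factors encode assistance, neutrality, interference", {
  expect_identical(interaction_factor("side_by_side", 100), 1)
  expect_identical(interaction_factor("alternating", 100), 0.5)
  expect_equal(interaction_factor("nested", 1e-12), 5, tolerance = 1e-9)
  expect_equal(interaction_factor("nested", 1e4), 1)
  d <- c(0.5, 2, 10)
  expect_true(all(interaction_factor("nested", d) > 1 &
                    interaction_factor("nested", d) <= 5))
  expect_error(interaction_factor("nested"), "needs d")
})

test_that("tracking increment is r * d and rejects negative ratios", {
  expect_identical(tracking_increment(0, 1500), 0)
  expect_identical(tracking_increment(0.1, 1500), 150)
  expect_identical(tracking_increment(0.15, 40), 6)
  expect_error(tracking_increment(-0.1, 10), "r must be")
})

test_that("rate sets follow the interaction/tracking construction", {
  cfg <- loop_config("side_by_side", d1 = 300, d2 = 1500, k1 = 1, k2 = 1)
  rs <- build_rate_set(cfg)
  expect_equal(rs$lam23, rs$lam14)
  expect_equal(rs$lam43, rs$lam12)
  expect_equal(rs$lam14, looping_rate(300))
  # nested preset at d1 scales the looped blue rate by 4 exp(-d1/2) + 1
  cfgn <- loop_config("nested", d1 = 3, d2 = 1500, k1 = "preset",
                      k1_dist = "d1", k2 = 0.5)
  rsn <- build_rate_set(cfgn)
  expect_equal(rsn$lam23, (4 * exp(-0.5 * 3) + 1) * rsn$lam14)
  expect_equal(rsn$lam43, 0.5 * rsn$lam12)
  # tracking adds exactly r * d to each looping rate
  cfg_t <- loop_config("alternating", d1 = 300, d2 = 1500, r = 0.1,
                       k1 = 0.5, k2 = 0.5)
  rs_t <- build_rate_set(cfg_t)
  expect_equal(rs_t$lam12 - rs$lam12, 150)
  expect_equal(rs_t$lam14 - looping_rate(300), 30)
  # the alternative reading leaves the derived rates untracked
  cfg_n <- cfg_t
  cfg_n$tracking_in_derived <- FALSE
  rs_n <- build_rate_set(cfg_n)
  expect_equal(rs_n$lam23, 0.5 * looping_rate(300))
  expect_equal(rs_t$lam23, 0.5 * (looping_rate(300) + 30))
})

test_that("configuration validation lists offending fields", {
  expect_error(loop_config("nested", d1 = -1), "d1")
  expect_error(loop_config("nested", d1 = 10, r = 1.2), "r \\(must be in")
  expect_error(loop_config("nested", d1 = 10, delta = 0), "delta")
  expect_error(loop_config("nested", d1 = 10, lam21 = -0.1), "lam21")
  expect_error(loop_config("nested", d1 = 10, k1 = "bogus"), "k1")
})

test_that("generator has the printed structure and conserves probability", {
  cfgs <- random_rate_configs(5, seed = 11)
  for (cc in cfgs) {
    gp <- build_generator(cc$rates, cc$mu1, cc$mu2)
    expect_equal(max(abs(colSums(gp$A))), 0, tolerance = 1e-12)
    expect_true(all(gp$A[row(gp$A) != col(gp$A)] >= 0))
    # square-cycle topology: no direct OFF1-ON2 or OFF2-ON1 edges
    expect_identical(gp$A[4, 1], 0)
    expect_identical(gp$A[1, 4], 0)
    expect_identical(gp$A[2, 3], 0)
    expect_identical(gp$A[3, 2], 0)
    expect_equal(diag(gp$Lambda), c(0, 0, cc$mu1, cc$mu2))
  }
  r <- rate_list(1.3, 0.7, 0.4, 2.2, 0.5, 1.1, 0.9, 0.6)
  A <- build_generator(r, 10, 10)$A
  expect_equal(A[3, 1], r$lam14)
  expect_equal(A[1, 3], r$lam41)
  expect_equal(A[2, 1], r$lam12)
  expect_equal(A[4, 2], r$lam23)
  expect_equal(A[4, 3], r$lam43)
  expect_equal(A[3, 4], r$lam34)
})

test_that("all-equal-rates generator has the symmetric-cycle spectrum", {
  lam <- 0.7
  gp <- build_generator(all_equal_rates(lam), 10, 10)
  ev <- sort(Re(eigen(gp$A)$values))
  expect_equal(ev, c(-4 * lam, -2 * lam, -2 * lam, 0), tolerance = 1e-10)
})

test_that("JSON configs round-trip with figure-style defaults", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pattern = "alternating", d1 = 300, k1 = 0.5,
                            k2 = 0.5), path, auto_unbox = TRUE)
  cfg <- read_config_json(path)
  expect_identical(cfg$pattern, "alternating")
  expect_identical(cfg$d2, 1500)
  expect_identical(cfg$r, 0)
  expect_identical(cfg$mu1, 10)
  expect_identical(cfg$lam41, 0.3)
  jsonlite::write_json(list(pattern = "nested", d1 = 10, bogus = 1), path,
                       auto_unbox = TRUE)
  expect_error(read_config_json(path), "unknown config keys")
})
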