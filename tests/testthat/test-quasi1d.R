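test_that("sigmoidal release rate has midpoint, asymptote and printed value", {
  # midpoint: at t = t_init the sigmoid is exactly 1/2
  expect_equal(release_rate(2, epsilon = 1, k_deg = -3e-5, t_init = 2),
               -3e-5 / 2)
  # asymptote: far past onset the rate approaches epsilon * k_deg
  expect_equal(release_rate(100, epsilon = 0.7, k_deg = -3e-5, t_init = 2),
               0.7 * -3e-5, tolerance = 1e-12)
  # direct evaluation at the optimal rate constant, 5 days past onset
  expect_equal(release_rate(1.932 + 5, 0.5, -2.4321e-5, 1.932),
               0.5 * -2.4321e-5 / (1 + exp(-5)), tolerance = 1e-12)
  expect_equal(round(release_rate(1.932 + 5, 0.5, -2.4321e-5, 1.932), 9),
               -1.2079e-5, tolerance = 1e-6)
  expect_error(release_rate(NaN, 0.5, -1e-5, 1), "finite")
  expect_error(release_rate(1, 0, -1e-5, 1))
})

test_that("MDD is zero without reaction and suppressed before onset", {
  cfg0 <- quasi1d_config(k_deg = 0, t_init = 1)
  expect_true(all(simulate_mdd(cfg0)$values == 0))

  cfg <- quasi1d_config(k_deg = -5e-6, t_init = 2)
  mdd <- simulate_mdd(cfg)
  expect_lt(ts_at_test(mdd, 1), 0.05 * ts_at_test(mdd, 28))
})

test_that("MDD is monotone, bounded by the Mg domain, and truncates", {
  cfg <- quasi1d_config(k_deg = -5e-6, t_init = 1.932)
  mdd <- simulate_mdd(cfg)
  expect_monotone_nondecreasing(mdd$values[, 1])
  expect_lte(max(mdd$values), cfg$r_initial * 1e6)
  expect_false(attr(mdd, "truncated"))

  # a fast-dissolving configuration consumes the 0.2 mm domain
  cfg_fast <- quasi1d_config(k_deg = -8e-5, t_init = 0.5)
  expect_warning(mdd_f <- simulate_mdd(cfg_fast), "consumed")
  expect_true(attr(mdd_f, "truncated"))
  expect_equal(max(mdd_f$values), cfg_fast$r_initial * 1e6)
})

test_that("late-time MDD slope matches the closed-form linear regime", {
  eps <- 0.5; k <- -5e-6
  cfg <- quasi1d_config(k_deg = k, t_init = 1, epsilon = eps)
  mdd <- simulate_mdd(cfg)
  n <- length(mdd$times)
  slope <- (mdd$values[n, 1] - mdd$values[n - 1, 1]) /
    (mdd$times[n] - mdd$times[n - 1])
  slope_exact <- eps * abs(k) * cfg$M_Mg / cfg$rho_Mg * 86400 * 1e6 # um/day
  expect_equal(slope, slope_exact, tolerance = 1e-6)
})

test_that("MDD at 28 days is insensitive to time-step refinement", {
  v <- vapply(c(400L, 800L), function(nt) {
    cfg <- quasi1d_config(k_deg = -5e-6, t_init = 1.932, n_t = nt)
    mdd <- simulate_mdd(cfg)
    mdd$values[nrow(mdd$values), 1]
  }, numeric(1))
  expect_lt(abs(v[2] - v[1]) / v[1], 0.005)
})

test_that("MDD is nondecreasing in |k_deg| at fixed time and t_init", {
  ks <- -c(1e-6, 5e-6, 2e-5, 6e-5)
  mdd28 <- vapply(ks, function(k) {
    cfg <- quasi1d_config(k_deg = k, t_init = 1.5)
    m <- suppressWarnings(simulate_mdd(cfg))
    m$values[nrow(m$values), 1]
  }, numeric(1))
  expect_monotone_nondecreasing(mdd28)
})

test_that("configuration invariants are enforced", {
  expect_error(quasi1d_config(k_deg = -1e-5, t_init = -1), "t_init")
  expect_error(quasi1d_config(k_deg = -1e-5, t_init = 1, epsilon = 1.2))
  expect_error(quasi1d_config(k_deg = -1e-5, t_init = 1, dl_init = 1e-3))
  expect_error(quasi1d_config(k_deg = Inf, t_init = 1), "finite")
})
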