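# helper: hand-built PCE with prescribed coefficients on the unit square
manual_pce <- function(coef, idx) {
  structure(list(coefficients = coef, index_set = idx, degree = max(idx),
                 q = 1, lower = c(0, 0), upper = c(1, 1), eps_loo = 0,
                 n_train = NA_integer_, ridge = 0, var_y = sum(coef[-1]^2)),
            class = "mguq_pce")
}

test_that("analytic Sobol indices follow the coefficient decomposition", {
  a <- 2; b <- 1.5; c <- 0.5
  m <- manual_pce(c(1, a, b, c),
                  rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  s <- sobol_from_pce(m)
  D <- a^2 + b^2 + c^2
  expect_equal(s$first_order, c(a^2, b^2) / D, tolerance = 1e-12)
  expect_equal(s$total, c(a^2 + c^2, b^2 + c^2) / D, tolerance = 1e-12)
  expect_true(all(s$first_order <= s$total + 1e-12))

  # additive model: S_i = S_T,i and the first-order indices sum to one
  add <- manual_pce(c(0.3, a, b), rbind(c(0, 0), c(1, 0), c(0, 1)))
  sa <- sobol_from_pce(add)
  expect_equal(sa$first_order, sa$total, tolerance = 1e-12)
  expect_equal(sum(sa$first_order), 1, tolerance = 1e-12)

  # single-input model carries all the variance
  one <- structure(list(coefficients = c(0, 1, 0.4),
                        index_set = rbind(0, 1, 2), degree = 2, q = 1,
                        lower = 0, upper = 1, eps_loo = 0, ridge = 0),
                   class = "mguq_pce")
  so <- sobol_from_pce(one)
  expect_equal(so$first_order, 1)
  expect_equal(so$total, 1)

  const <- manual_pce(c(1, 0, 0, 0),
                      rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  expect_error(sobol_from_pce(const), "undefined")
})

test_that("MC estimator agrees with the analytic PCE decomposition", {
  a <- 2; b <- 1.5; c <- 0.5
  m <- manual_pce(c(1, a, b, c),
                  rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
  exact <- sobol_from_pce(m)
  mc <- sobol_mc(m, unit_space(2), n = 2048, seed = 17)
  expect_lt(max(abs(mc$first_order - exact$first_order) /
                  pmax(mc$se_first, 1e-3)), 3)
  expect_lt(max(abs(mc$total - exact$total) / pmax(mc$se_total, 1e-3)), 3)
})

test_that("MC indices of an ignored parameter are within 3 SE of zero", {
  f <- function(M) sin(2 * M[, 1])  # second input unused
  mc <- sobol_mc(f, unit_space(2), n = 2048, seed = 23)
  expect_lt(abs(mc$first_order[2]) / max(mc$se_first[2], 1e-3), 3)
  expect_lt(abs(mc$total[2]) / max(mc$se_total[2], 1e-3), 3)
})

test_that("MC indices of a linear additive model match variance ratios", {
  f <- function(M) 3 * M[, 1] - 2 * M[, 2]
  # Var contributions 9/12 and 4/12
  mc <- sobol_mc(f, unit_space(2), n = 4096, seed = 29)
  expect_lt(max(abs(mc$first_order - c(9, 4) / 13) /
                  pmax(mc$se_first, 1e-3)), 3)
  expect_lt(max(abs(mc$total - c(9, 4) / 13) / pmax(mc$se_total, 1e-3)), 3)
  expect_error(sobol_mc(function(M) rep(1, nrow(M)), unit_space(2),
                        n = 128, seed = 1), "degenerate")
})

test_that("analytic indices are invariant to rescaling the physical bounds", {
  X <- sample_one_shot(unit_space(2), 30, "lhs", seed = 41)$points
  Y <- apply(X, 1, smooth_fn)
  pc1 <- fit_pce(X, Y, space = unit_space(2), degree_range = 1:4)
  sp2 <- parameter_space(c("x1", "x2"), c(-10, 100), c(10, 300))
  X2 <- space_unscale_test(sp2, X)
  pc2 <- fit_pce(X2, Y, space = sp2, degree_range = 1:4)
  s1 <- sobol_from_pce(pc1); s2 <- sobol_from_pce(pc2)
  expect_equal(s1$first_order, s2$first_order, tolerance = 1e-8)
  expect_equal(s1$total, s2$total, tolerance = 1e-8)
})
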