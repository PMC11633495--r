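test_that("hyperbolic index sets match enumeration and the count formula", {
  expect_equal(nrow(build_index_set(1, 3, 1)), 4)
  expect_equal(sort(build_index_set(1, 3, 1)[, 1]), 0:3)
  # q = 1 count is (p + n)! / (p! n!)
  expect_equal(nrow(build_index_set(2, 3, 1)), choose(5, 2))
  expect_equal(nrow(build_index_set(3, 4, 1)), choose(7, 3))

  # q = 0.5 is the subset of the q = 1 set passing the norm check
  full <- build_index_set(2, 3, 1)
  hyp <- build_index_set(2, 3, 0.5)
  keep <- rowSums(full^0.5)^2 <= 3 + 1e-12
  expect_equal(nrow(hyp), sum(keep))
  expect_true(all(apply(hyp, 1, paste, collapse = ",") %in%
                    apply(full[keep, , drop = FALSE], 1, paste,
                          collapse = ",")))
  expect_error(build_index_set(2, 3, 0))
  expect_error(build_index_set(2, 3, 1.5))
})

test_that("the Legendre basis is orthonormal under the uniform measure", {
  skip_if_not_installed("pracma")
  gl <- pracma::gaussLegendre(32, -1, 1)
  Psi <- mguq:::legendre_orthonormal(gl$x, 6)
  G <- crossprod(Psi * gl$w, Psi) / 2   # E[psi_a psi_b], density 1/2
  expect_lt(max(abs(G - diag(7))), 1e-8)
})

test_that("PCE reproduces constants and exact polynomials", {
  X <- sample_one_shot(unit_space(2), 20, "lhs", seed = 1)$points
  suppressWarnings({
    pc <- fit_pce(X, rep(4.2, 20), space = unit_space(2), degree_range = 1:2)
  })
  expect_equal(pc$coefficients[1], 4.2, tolerance = 1e-10)
  expect_lt(max(abs(pc$coefficients[-1])), 1e-10)
  expect_equal(pc$eps_loo, 0)

  Y <- apply(X, 1, quad_fn)
  pc2 <- fit_pce(X, Y, space = unit_space(2), degree_range = 1:4, q = 1)
  Xt <- sample_one_shot(unit_space(2), 40, "mc", seed = 2)$points
  expect_equal(predict(pc2, Xt), apply(Xt, 1, quad_fn), tolerance = 1e-10)
  expect_equal(pc2$degree, 2)
})

test_that("least-squares coefficients match the normal-equations oracle", {
  sp <- model_parameter_space(1)
  X <- sample_one_shot(sp, 25, "lhs", seed = 5)$points
  fn <- degradation_model_fn(1)
  Y <- apply(X, 1, function(r) { names(r) <- sp$names; fn(r) })
  pc <- fit_pce(X, Y, space = sp, degree_range = 3, q = 1)

  # independent refit: explicit orthonormal Legendre basis + solve()
  U <- sweep(sweep(X, 2, (sp$lower + sp$upper) / 2), 2,
             (sp$upper - sp$lower) / 2, `/`)
  leg <- function(u, k) switch(k + 1L, rep(1, length(u)), u,
                               (3 * u^2 - 1) / 2, (5 * u^3 - 3 * u) / 2)
  Psi <- apply(pc$index_set, 1, function(a)
    sqrt(2 * a[1] + 1) * leg(U[, 1], a[1]) *
      sqrt(2 * a[2] + 1) * leg(U[, 2], a[2]))
  beta <- solve(crossprod(Psi), crossprod(Psi, Y))
  pred_oracle <- as.numeric(Psi %*% beta)
  expect_equal(predict(pc, X), pred_oracle, tolerance = 1e-8)
})

test_that("rank-deficient designs fall back to ridge with a warning", {
  X <- matrix(rep(seq(0, 1, length.out = 8), 2), ncol = 2)  # x1 == x2
  Y <- X[, 1]^2
  expect_warning(fit_pce(X, Y, space = unit_space(2), degree_range = 2,
                         q = 1), "ridge")
})

test_that("degrees too rich for the sample are skipped or rejected", {
  X <- sample_one_shot(unit_space(2), 5, "lhs", seed = 1)$points
  Y <- apply(X, 1, quad_fn)
  pc <- fit_pce(X, Y, space = unit_space(2), degree_range = 1:6, q = 1)
  expect_lte(nrow(pc$index_set), 5)
  expect_error(fit_pce(X, Y, space = unit_space(2), degree_range = 6, q = 1),
               "n_train")
})
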