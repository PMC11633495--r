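test_that("wt% normalisation: symmetry, single element, direct values", {
  expect_equal(unname(wt_percent(rep(3, 6))), rep(100 / 6, 6))
  one <- wt_percent(c(0, 0, 5, 0, 0, 0))
  expect_equal(unname(one), c(0, 0, 100, 0, 0, 0))
  expect_equal(unname(wt_percent(1:6)), 100 * (1:6) / 21, tolerance = 1e-12)
  expect_equal(sum(wt_percent(stats::runif(6))), 100, tolerance = 1e-9)
  expect_error(wt_percent(rep(0, 6)), "all element masses")
  expect_error(wt_percent(c(-1, 1, 1, 1, 1, 1)))
})

test_that("hydrogen bookkeeping credits exactly one H2 per Mg", {
  expect_identical(h2_from_mg(1), 1)
  expect_identical(h2_from_mg(2.5), 2.5)
  expect_identical(h2_from_mg(c(0, 3)), c(0, 3))
  expect_error(h2_from_mg(-1))
  res <- suppressWarnings(simulate_precipitation(tiny_precip_config()))
  expect_identical(res$audit$h2_evolved, res$audit$mg_released)
})

test_that("zero reaction constants give pure diffusion and no precipitate", {
  cfg <- tiny_precip_config(k_rxn = rep(0, 6))
  res <- suppressWarnings(simulate_precipitation(cfg))
  expect_true(all(res$precipitates == 0))
  expect_true(all(is.na(res$wt$values)))        # no solid mass anywhere
  # H+ takes part only in reactions, so its total is conserved exactly
  h_total <- sum(res$dissolved[, "H"] * res$grid$dx)
  expect_equal(h_total, cfg$c0[["H"]] * sum(res$grid$dx), tolerance = 1e-9)
})

test_that("single-reaction kinetics match an independent stiff-ODE solution", {
  skip_if_not_installed("deSolve")
  k1 <- 5e-8; Keq <- 5; epsv <- 0.5
  sp_tab <- mguq:::mguq_species()
  sp_tab$D <- rep(1e-30, 6)                     # effectively no transport
  cfg <- precipitation_config(
    k_deg = 0, t_init = 1, k_rxn = c(k1, 0, 0, 0, 0, 0),
    K_eq = c(Keq, 1, 1, 1, 1, 1), epsilon = epsv,
    c0 = c(Mg = 1, OH = 2, H = 1e-4, HCO3 = 1e-4, Ca = 1e-4, HPO4 = 1e-4),
    species = sp_tab, D_dl = 0, n_x_dl = 3L, n_x_el = 6L, n_t = 800L)
  res <- simulate_precipitation(cfg, output_times = c(0, 28))
  p_end <- res$precipitates[1, "brucite"]

  ode <- deSolve::lsoda(
    y = c(p = 0, mg = 1, oh = 2),
    times = c(0, 28 * 86400),
    func = function(t, y, parms) {
      dp <- epsv * k1 * (Keq - y["mg"] * y["oh"])
      list(c(dp, -dp, -2 * dp))
    }, rtol = 1e-10, atol = 1e-12)
  p_ref <- unname(ode[2, "p"])
  expect_gt(p_ref, 0)
  expect_equal(unname(p_end), p_ref, tolerance = 0.01)
  # every DL cell is identical without transport
  expect_equal(res$precipitates[, "brucite"],
               rep(p_end, 3), ignore_attr = TRUE)
})

test_that("magnesium is conserved across dissolution and precipitation", {
  res <- suppressWarnings(simulate_precipitation(tiny_precip_config()))
  a <- res$audit
  expect_gt(a$mg_released, 0)
  rel_err <- abs(a$mg_released - (a$mg_dissolved + a$mg_precipitated)) /
    a$mg_released
  expect_lt(rel_err, 1e-3)
})

test_that("closed system without source conserves every species", {
  cfg <- tiny_precip_config(k_rxn = rep(0, 6))
  cfg$k_deg <- 0
  res <- simulate_precipitation(cfg)
  totals <- colSums(res$dissolved * res$grid$dx)
  expect_equal(unname(totals), unname(cfg$c0 * sum(res$grid$dx)),
               tolerance = 1e-9)
})

test_that("recorded wt%% rows sum to 100 once solid mass exists", {
  res <- suppressWarnings(simulate_precipitation(tiny_precip_config()))
  sums <- rowSums(res$wt$values)
  sums <- sums[!is.na(sums)]
  expect_gt(length(sums), 0)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("electromigration step preserves mass and nonnegativity", {
  cfg <- tiny_precip_config(migration_enabled = TRUE, n_t = 100L)
  res <- suppressWarnings(simulate_precipitation(cfg, output_times = c(0, 28)))
  expect_true(all(res$dissolved >= 0))
  a <- res$audit
  expect_lt(abs(a$mg_released - (a$mg_dissolved + a$mg_precipitated)) /
              a$mg_released, 5e-3)
})

test_that("species table validation rejects wrong charges", {
  sp_tab <- mguq:::mguq_species()
  sp_tab$z[1] <- 1L
  expect_error(precipitation_config(k_deg = -1e-5, t_init = 1,
                                    species = sp_tab), "charges")
})
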