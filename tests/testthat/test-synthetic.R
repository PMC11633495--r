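test_that("noiseless datasets equal the simulator output exactly", {
  ds <- make_mdd_dataset(-8e-6, 1.2, noise_sd = 0, seed = 1)
  clean <- degradation_traj_fn(1, times = ds$observations$times,
                               resolution = "default")(ds$true_params)
  expect_equal(as.numeric(ds$observations$values), unname(clean),
               tolerance = 1e-12)

  cfgv <- tiny_diffusion_config(D_Mg = 6.05e-9)
  dv <- make_vl_dataset(6.05e-9, noise_sd = 0, seed = 1, config = cfgv)
  vl <- simulate_volume_loss(cfgv, output_times = dv$observations$times)
  expect_equal(as.numeric(dv$observations$values), as.numeric(vl$values),
               tolerance = 1e-12)
})

test_that("datasets are reproducible per seed and differ across seeds", {
  a <- make_mdd_dataset(-8e-6, 1.2, seed = 7)
  b <- make_mdd_dataset(-8e-6, 1.2, seed = 7)
  c <- make_mdd_dataset(-8e-6, 1.2, seed = 8)
  expect_identical(a$observations$values, b$observations$values)
  expect_false(identical(a$observations$values, c$observations$values))
})

test_that("empirical noise level matches the requested 5%", {
  clean <- degradation_traj_fn(1, times = c(7, 14, 21, 28),
                               resolution = "default")(
                                 c(k_deg = -8e-6, t_init = 1.2))
  rel <- vapply(1:1000, function(s) {
    ds <- make_mdd_dataset(-8e-6, 1.2, noise_sd = 0.05, seed = s)
    as.numeric(ds$observations$values) / clean - 1
  }, numeric(4))
  expect_lt(abs(stats::sd(rel) - 0.05) / 0.05, 0.10)
})

test_that("wt%% observations are renormalised and VL is clipped", {
  p <- c(k_deg = -2.4321e-5, t_init = 1.932, k1 = -9e-21, k2 = -7e-9,
         k3 = -7e-10, k4 = -1.08e-2, k5 = -8e-24, k6 = 9e16)
  ds <- make_wt_dataset(p, noise_sd = 0.05, seed = 3,
                        config = tiny_precip_config())
  expect_equal(sum(ds$observations$values), 100, tolerance = 1e-9)
  expect_named(as.data.frame(ds$observations)[-1],
               c("Mg", "O", "P", "C", "Ca"))

  dv <- make_vl_dataset(1e-5, noise_sd = 0.5, seed = 4,
                        config = tiny_diffusion_config(1e-5))
  expect_true(all(dv$observations$values >= 0 &
                    dv$observations$values <= 100))
})

test_that("ground truth outside the testing ranges is rejected", {
  expect_error(make_mdd_dataset(-1, 1), "ranges")
  expect_error(make_mdd_dataset(-8e-6, 5), "ranges")
  expect_error(make_vl_dataset(1), "range")
})

test_that("noiseless calibration closes the loop on volume loss", {
  cfg <- tiny_diffusion_config()
  truth <- 6.05e-9
  ds <- make_vl_dataset(truth, noise_sd = 0, seed = 5, config = cfg)
  sp <- model_parameter_space(3)
  predict_vl <- function(theta) {
    cfg2 <- cfg; cfg2$D_Mg <- theta[["D_Mg"]]
    as.numeric(simulate_volume_loss(cfg2,
                                    output_times = ds$observations$times)$values)
  }
  cal <- calibrate(predict_vl, ds$observations, sp, n_screen = 60, seed = 6)
  expect_lt(abs(cal$par[["D_Mg"]] - truth) / truth, 0.01)
})

test_that("dataset files round-trip through CSV plus JSON sidecar", {
  ds <- make_mdd_dataset(-8e-6, 1.2, seed = 9)
  path <- file.path(tempdir(), "mdd.csv")
  write_synth_dataset(ds, path)
  back <- read_time_series(path)
  expect_equal(back$values, ds$observations$values, ignore_attr = TRUE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$true_params$k_deg, -8e-6)
  expect_equal(side$seed, 9)
  unlink(c(path, paste0(path, ".json")))
})
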