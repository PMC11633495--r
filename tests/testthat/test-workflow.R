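test_that("the end-to-end workflow writes a complete, consistent manifest", {
  out <- tempfile("wf_")
  # SA is exercised in the dispatch test below; the model-3 response over
  # its full testing range is near-constant (saturated volume loss), which
  # the MC Sobol estimator rejects by design
  mf <- run_workflow(list(model = 3, surrogate = "kriging",
                          doe = list(method = "adaptive", n_initial = 5,
                                     budget = 8),
                          tasks = "propagate", propagate_n = 100),
                     out_dir = out, seed = 42)
  expect_identical(mf$status, "ok")
  expect_true(all(file.exists(mf$artifacts)))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(mf$timings$T_sim,
               mf$timings$T_BB + mf$timings$T_SM + mf$timings$T_opt +
                 mf$timings$T_C + mf$timings$T_I, tolerance = 1e-9)
  # reloadable surrogate artifact
  s <- read_surrogate(file.path(out, "surrogate.json"))
  expect_s3_class(s, "mguq_kriging")
  unlink(out, recursive = TRUE)
})

test_that("identical configuration and seed give identical artifacts", {
  cfgl <- list(model = 1, surrogate = "pce",
               doe = list(method = "lhs", n_samples = 15),
               tasks = c("sa", "propagate"), sa_n = 128, propagate_n = 50)
  o1 <- tempfile("wf1_"); o2 <- tempfile("wf2_")
  run_workflow(cfgl, out_dir = o1, seed = 7)
  run_workflow(cfgl, out_dir = o2, seed = 7)
  for (f in c("design.csv", "surrogate.json", "sobol.csv",
              "propagation.csv")) {
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)), label = f)
  }
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("Sobol dispatch follows the surrogate family", {
  o1 <- tempfile("wfa_"); o2 <- tempfile("wfb_")
  run_workflow(list(model = 1, surrogate = "pce",
                    doe = list(method = "lhs", n_samples = 15), tasks = "sa"),
               out_dir = o1, seed = 3)
  run_workflow(list(model = 1, surrogate = "kriging",
                    doe = list(method = "lhs", n_samples = 12), tasks = "sa",
                    sa_n = 128),
               out_dir = o2, seed = 3)
  s1 <- utils::read.csv(file.path(o1, "sobol.csv"))
  s2 <- utils::read.csv(file.path(o2, "sobol.csv"))
  expect_true(all(s1$estimator == "analytic-pce"))
  expect_true(all(s2$estimator == "mc-pick-freeze"))
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("unknown configuration keys are rejected fail-fast", {
  expect_error(run_workflow(list(modle = 1)), "unknown configuration key")
  expect_error(run_workflow(list(doe = list(foo = 1))), "unknown")
})

test_that("YAML configurations load with defaults merged", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("model: 3", "surrogate: pck", "doe:", "  method: lhs",
               "  n_samples: 12"), tmp)
  cfg <- read_workflow_config(tmp)
  expect_identical(cfg$model, 3L)
  expect_identical(cfg$surrogate, "pck")
  expect_identical(cfg$doe$method, "lhs")
  expect_identical(cfg$doe$theta, 1e-4)   # default preserved
  unlink(tmp)
})

test_that("the calibration task produces an optimum inside the bounds", {
  out <- tempfile("wfc_")
  mf <- run_workflow(list(model = 1, surrogate = "kriging",
                          doe = list(method = "lhs", n_samples = 20),
                          tasks = "calibrate"),
                     out_dir = out, seed = 11)
  expect_identical(mf$status, "ok")
  cal <- jsonlite::read_json(file.path(out, "calibration.json"),
                             simplifyVector = TRUE)
  sp <- model_parameter_space(1)
  expect_true(cal$par$k_deg >= sp$lower[1] && cal$par$k_deg <= sp$upper[1])
  expect_true(cal$par$t_init >= sp$lower[2] && cal$par$t_init <= sp$upper[2])
  expect_true(is.finite(cal$objective))
  unlink(out, recursive = TRUE)
})

test_that("the command-line entry point ships with the package", {
  cli <- system.file("cli", "mguq.R", package = "mguq")
  expect_true(nzchar(cli) && file.exists(cli))
})
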