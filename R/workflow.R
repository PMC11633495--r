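# Workflow orchestration: DOE -> simulator evaluations -> surrogate fit ->
# UQ tasks (sensitivity analysis, propagation, calibration), with one master
# seed spawning per-stage substreams, and a run manifest recording the
# configuration echo, per-phase wall times and every artifact written.

#' Scalar quantity-of-interest evaluator for a degradation model
#'
#' Builds the black-box function used by the DOE and surrogate stages:
#' model 1 returns MDD (um) at `day`; model 2 the wt% of `element` in the
#' degradation layer at `day`; model 3 the volume loss (%) at `day`.
#' The `"coarse"` resolution presets keep single evaluations well under a
#' second so that sampling studies stay desk-scale.
#'
#' @param model Integer 1, 2 or 3.
#' @param day Evaluation day (defaults: 28, 28, 56).
#' @param element Element for model 2 (default `"Mg"`).
#' @param resolution `"coarse"` or `"default"` grid preset.
#' @param model_params Named list of configuration overrides applied on top
#'   of the preset.
#' @return Function mapping a named parameter vector to a scalar QoI.
#' @export
degradation_model_fn <- function(model, day = NULL, element = "Mg",
                                 resolution = c("coarse", "default"),
                                 model_params = list()) {
  resolution <- match.arg(resolution)
  model <- as.integer(model)
  day <- day %||% c(28, 28, 56)[model]
  traj <- degradation_traj_fn(model, times = day, element = element,
                              resolution = resolution,
                              model_params = model_params)
  function(theta) as.numeric(traj(theta))[length(day)]
}

#' Trajectory evaluator for a degradation model
#'
#' Like [degradation_model_fn()] but returning the QoI at several times at
#' once (for model 2, `element` may be a vector and the result is the wt%
#' composition at `times`).
#'
#' @inheritParams degradation_model_fn
#' @param times Days at which to evaluate (model 2: single day).
#' @return Function mapping a named parameter vector to a numeric vector.
#' @export
degradation_traj_fn <- function(model, times, element = "Mg",
                                resolution = c("coarse", "default"),
                                model_params = list()) {
  resolution <- match.arg(resolution)
  model <- as.integer(model)
  apply_over <- function(cfg) {
    for (nm in names(model_params)) {
      if (!nm %in% names(cfg))
        stop(sprintf("unknown model parameter '%s'", nm), call. = FALSE)
      cfg[[nm]] <- model_params[[nm]]
    }
    cfg
  }
  if (model == 1L) {
    function(theta) {
      cfg <- quasi1d_config(k_deg = theta[["k_deg"]],
                            t_init = theta[["t_init"]],
                            n_t = if (resolution == "coarse") 200L else 400L)
      cfg <- apply_over(cfg)
      ts_at(suppressWarnings(simulate_mdd(cfg)), times)
    }
  } else if (model == 2L) {
    function(theta) {
      cfg <- precipitation_config(
        k_deg = theta[["k_deg"]], t_init = theta[["t_init"]],
        k_rxn = unname(theta[paste0("k", 1:6)]),
        n_x_dl = if (resolution == "coarse") 6L else 8L,
        n_x_el = if (resolution == "coarse") 18L else 24L,
        n_t = if (resolution == "coarse") 600L else 1200L,
        n_sub = if (resolution == "coarse") 3L else 6L)
      cfg <- apply_over(cfg)
      wt6 <- suppressWarnings(dl_composition(cfg, day = max(times)))
      wt5 <- wt6[c("Mg", "O", "P", "C", "Ca")]
      (100 * wt5 / sum(wt5))[element]
    }
  } else if (model == 3L) {
    function(theta) {
      cfg <- diffusion_config(
        D_Mg = theta[["D_Mg"]],
        geometry = if (resolution == "coarse")
          geom_cylinder(nr = 12L, nz = 18L) else geom_cylinder(),
        n_t = if (resolution == "coarse") 60L else 120L)
      cfg <- apply_over(cfg)
      ts_at(simulate_volume_loss(cfg), times)
    }
  } else stop("'model' must be 1, 2 or 3", call. = FALSE)
}

surrogate_factory_for <- function(family, space, seed = NULL) {
  switch(family,
         kriging = function(X, Y) fit_kriging(X, Y, space = space,
                                              seed = seed),
         pce = function(X, Y) fit_pce(X, Y, space = space),
         pck = function(X, Y) fit_pck(X, Y, space = space, seed = seed),
         stop("surrogate must be kriging, pce or pck", call. = FALSE))
}

workflow_config_defaults <- function() {
  list(model = 1L, surrogate = "kriging", qoi_day = NULL, element = "Mg",
       resolution = "coarse",
       doe = list(method = "adaptive", n_samples = NULL, theta = 1e-4,
                  budget = NULL, n_initial = NULL),
       tasks = c("sa", "propagate"),
       sa_n = 512L, propagate_n = 500L,
       calibration = list(true_params = NULL, noise_sd = 0.05),
       model_params = list())
}

merge_config <- function(user, defaults) {
  for (nm in names(user)) {
    if (!nm %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", nm), call. = FALSE)
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      merge_config(user[[nm]], defaults[[nm]]) else user[[nm]]
  }
  defaults
}

#' Read a workflow configuration file
#'
#' YAML with keys mirroring [run_workflow()]'s configuration list; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_workflow_config <- function(path) {
  merge_config(yaml::read_yaml(path), workflow_config_defaults())
}

#' Run the full UQ workflow
#'
#' Executes the four workflow steps for one degradation model: design of
#' experiments (one-shot or adaptive), simulator evaluations, surrogate
#' construction, and the requested UQ tasks (Sobol sensitivity analysis,
#' uncertainty propagation, calibration against a synthetic dataset). Sobol
#' indices use the analytic PCE path for PCE/PCK surrogates and pick-freeze
#' Monte Carlo for Kriging. All randomness derives from the single master
#' seed.
#'
#' @param config Configuration list (see [read_workflow_config()]) or a YAML
#'   path. Keys: `model` (1/2/3), `surrogate` (kriging/pce/pck), `qoi_day`,
#'   `element`, `resolution`, `doe` (method, n_samples, theta, budget, n_initial),
#'   `tasks` (subset of sa/propagate/calibrate), `sa_n`, `propagate_n`,
#'   `calibration` (true_params, noise_sd), `model_params`.
#' @param out_dir Output directory for artifacts (created if needed).
#' @param seed Master seed.
#' @return The run manifest (class `mguq_manifest`), also written to
#'   `manifest.json`.
#' @export
run_workflow <- function(config = list(), out_dir = tempfile("mguq_run_"),
                         seed = 1L) {
  if (is.character(config)) config <- read_workflow_config(config)
  else config <- merge_config(config, workflow_config_defaults())
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- as.integer(config$model)
  space <- model_parameter_space(model)
  day <- config$qoi_day %||% c(28, 28, 56)[model]
  fn <- degradation_model_fn(model, day = day, element = config$element,
                             resolution = config$resolution,
                             model_params = config$model_params)
  artifacts <- character(0)
  timings <- c(T_BB = 0, T_SM = 0, T_opt = 0, T_C = 0, T_I = 0)
  note <- function(path) artifacts <<- c(artifacts, path)
  clock <- function(key, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[key] <<- timings[[key]] + proc.time()[["elapsed"]] - t0
    out
  }

  # --- step 1+2: DOE and simulator evaluations
  doe <- config$doe
  failed_stage <- NULL
  result <- tryCatch({
    if (identical(doe$method, "adaptive")) {
      n_init <- as.integer(doe$n_initial %||% (10L * space$dim))
      budget <- as.integer(doe$budget %||% min_one_shot_size(space$dim))
      ad <- clock("T_BB", adaptive_sample(
        fn, space, surrogate_factory_for(config$surrogate, space,
                                         seed = derive_seed(seed, 3L)),
        theta = doe$theta, budget = budget, n_initial = n_init,
        seed = derive_seed(seed, 2L)))
      X <- ad$X; Y <- ad$Y; surrogate <- ad$surrogate
      hist_path <- file.path(out_dir, "adaptive_history.json")
      jsonlite::write_json(
        list(eps_history = ad$eps_history, best_history = ad$best_history,
             stop_reason = ad$stop_reason, n_initial = ad$n_initial,
             theta = ad$theta, budget = ad$budget),
        hist_path, auto_unbox = TRUE, digits = NA)
      note(hist_path)
    } else {
      n <- as.integer(doe$n_samples %||% min_one_shot_size(space$dim))
      X <- sample_one_shot(space, n, doe$method,
                           seed = derive_seed(seed, 2L))$points
      Y <- clock("T_BB", apply(X, 1, function(r) {
        names(r) <- space$names; fn(r)
      }))
      surrogate <- clock("T_SM", surrogate_factory_for(
        config$surrogate, space, seed = derive_seed(seed, 3L))(X, Y))
    }
    design_path <- file.path(out_dir, "design.csv")
    utils::write.csv(cbind(as.data.frame(X), qoi = Y), design_path,
                     row.names = FALSE)
    note(design_path)
    sur_path <- file.path(out_dir, "surrogate.json")
    write_surrogate(surrogate, sur_path)
    note(sur_path)

    # --- step 3/4: UQ tasks
    if ("sa" %in% config$tasks) {
      sob <- if (inherits(surrogate, c("mguq_pce", "mguq_pck")))
        sobol_from_pce(surrogate)
      else sobol_mc(surrogate, space, n = as.integer(config$sa_n),
                    seed = derive_seed(seed, 4L))
      sob_path <- file.path(out_dir, "sobol.csv")
      utils::write.csv(sobol_as_df(sob, params = space$names,
                                   qoi = sprintf("day%g", day)),
                       sob_path, row.names = FALSE)
      note(sob_path)
    }
    if ("propagate" %in% config$tasks) {
      pr <- propagate(surrogate, space, n = as.integer(config$propagate_n),
                      seed = derive_seed(seed, 5L))
      pr_path <- file.path(out_dir, "propagation.csv")
      utils::write.csv(data.frame(
        stat = c("mean", "variance", "sd", names(pr$quantiles)),
        value = c(pr$mean, pr$variance, pr$sd, unname(pr$quantiles))),
        pr_path, row.names = FALSE)
      note(pr_path)
    }
    if ("calibrate" %in% config$tasks) {
      cal <- clock("T_opt",
                   workflow_calibrate(model, config, space, X, seed))
      cal_path <- file.path(out_dir, "calibration.json")
      jsonlite::write_json(list(par = as.list(cal$par),
                                objective = cal$objective,
                                n_eval = cal$n_eval),
                           cal_path, auto_unbox = TRUE, digits = NA)
      note(cal_path)
    }
    "ok"
  }, error = function(e) {
    failed_stage <<- conditionMessage(e)
    "failed"
  })

  manifest <- structure(list(
    config = config, seed = seed, status = result,
    error = failed_stage,
    timings = c(as.list(timings), T_sim = sum(timings)),
    artifacts = artifacts,
    version = as.character(utils::packageVersion("mguq"))),
    class = "mguq_manifest")
  jsonlite::write_json(
    manifest[c("config", "seed", "status", "error", "timings", "artifacts",
               "version")],
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  manifest$out_dir <- out_dir
  manifest
}

# calibration task: synthetic dataset at the configured ground truth,
# per-time surrogates on the existing design, NRMSE minimisation
workflow_calibrate <- function(model, config, space, X, seed) {
  truth <- config$calibration$true_params
  noise_sd <- config$calibration$noise_sd
  dseed <- derive_seed(seed, 6L)
  if (model == 1L) {
    truth <- truth %||% list(k_deg = -2.4321e-5, t_init = 1.932)
    ds <- make_mdd_dataset(truth$k_deg, truth$t_init, noise_sd = noise_sd,
                           seed = dseed)
    times <- ds$observations$times
    traj <- degradation_traj_fn(1, times, resolution = config$resolution)
  } else if (model == 3L) {
    truth <- truth %||% list(D_Mg = 6.05e-9)
    ds <- make_vl_dataset(truth$D_Mg, noise_sd = noise_sd, seed = dseed)
    times <- ds$observations$times
    traj <- degradation_traj_fn(3, times, resolution = config$resolution)
  } else {
    truth <- truth %||% as.list(c(k_deg = -2.4321e-5, t_init = 1.932,
                                  k1 = -9.0245e-21, k2 = -7.0332e-9,
                                  k3 = -7.0023e-10, k4 = -1.0798e-2,
                                  k5 = -8.0037e-24, k6 = 9.001e16))
    ds <- make_wt_dataset(unlist(truth), noise_sd = noise_sd, seed = dseed)
    traj <- degradation_traj_fn(2, 28,
                                element = colnames(ds$observations$values),
                                resolution = config$resolution)
  }
  Y_mat <- t(apply(X, 1, function(r) { names(r) <- space$names; traj(r) }))
  models <- fit_time_surrogates(X, Y_mat, space, method = config$surrogate,
                                seed = derive_seed(seed, 8L))
  calibrate(time_surrogate_predictor(models), ds$observations, space,
            seed = derive_seed(seed, 9L))
}

#' @export
print.mguq_manifest <- function(x, ...) {
  cat(sprintf("<mguq_manifest> model %s + %s surrogate: %s\n",
              x$config$model, x$config$surrogate, x$status))
  cat(sprintf("  T_sim = %.2fs (BB %.2f, SM %.2f, opt %.2f)\n",
              x$timings$T_sim, x$timings$T_BB, x$timings$T_SM,
              x$timings$T_opt))
  cat("  artifacts:", length(x$artifacts), "file(s)\n")
  invisible(x)
}
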