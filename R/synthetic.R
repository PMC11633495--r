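# Synthetic "experimental" calibration datasets with known ground truth, so
# calibration, NRMSE computation and the full workflow are testable without
# proprietary measurement data. Sampling cadence mimics typical degradation
# experiments: weekly over 28 days, extended to 42/56 days for volume loss.

new_synth <- function(true_params, obs, noise_model, seed, replicates) {
  structure(list(true_params = true_params, observations = obs,
                 noise_model = noise_model, seed = seed,
                 replicates = replicates),
            class = "mguq_synth")
}

#' @export
print.mguq_synth <- function(x, ...) {
  cat("<mguq_synth>", x$observations$qoi_label, "dataset; truth:\n")
  print(signif(x$true_params, 5))
  invisible(x)
}

apply_noise <- function(v, noise_sd, noise_model) {
  if (noise_sd == 0) return(v)
  if (noise_model == "relative") v * (1 + stats::rnorm(length(v), 0, noise_sd))
  else v + stats::rnorm(length(v), 0, noise_sd)
}

#' Synthetic mean-degradation-depth dataset (model 1)
#'
#' Simulates the quasi-1D pure-Mg model at the requested ground-truth
#' parameters and adds i.i.d. Gaussian noise (relative by default, emulating
#' measurement scatter that scales with the degradation depth).
#'
#' @param k_deg,t_init Ground-truth parameters; must lie inside the model-1
#'   testing ranges.
#' @param noise_sd Noise standard deviation (relative fraction by default).
#' @param seed Seed for the noise draw.
#' @param times Observation days (default weekly over 28 days).
#' @param noise_model `"relative"` or `"additive"`.
#' @param config Optional [quasi1d_config()] template; `k_deg`/`t_init` are
#'   substituted in.
#' @return A `mguq_synth` object whose `observations` element is a noisy MDD
#'   [time_series()].
#' @export
make_mdd_dataset <- function(k_deg, t_init, noise_sd = 0.05, seed = NULL,
                             times = c(7, 14, 21, 28),
                             noise_model = c("relative", "additive"),
                             config = NULL) {
  noise_model <- match.arg(noise_model)
  sp <- model_parameter_space(1)
  if (!space_contains(sp, matrix(c(k_deg, t_init), 1)))
    stop("true parameters outside the model-1 testing ranges", call. = FALSE)
  cfg <- config %||% quasi1d_config(k_deg = k_deg, t_init = t_init)
  cfg$k_deg <- k_deg; cfg$t_init <- t_init
  mdd <- suppressWarnings(simulate_mdd(cfg))
  clean <- ts_at(mdd, times)
  noisy <- with_seed(seed, apply_noise(clean, noise_sd, noise_model))
  new_synth(c(k_deg = k_deg, t_init = t_init),
            time_series(times, noisy, qoi_label = "MDD_um"),
            list(type = noise_model, sd = noise_sd), seed, 1L)
}

#' Synthetic degradation-layer composition dataset (model 2)
#'
#' Generates the 5-element (Mg, O, P, C, Ca) wt% composition of the
#' degradation layer at day 28 under the ground-truth kinetics, adds noise,
#' and renormalises the row to sum to 100 (compositions are closed).
#'
#' @param params Named ground-truth vector with entries `k_deg`, `t_init`,
#'   `k1`..`k6`, inside the model-2 testing ranges.
#' @param noise_sd,seed,noise_model As in [make_mdd_dataset()].
#' @param day Observation day (default 28).
#' @param config Optional [precipitation_config()] template.
#' @return A `mguq_synth` with a 1-row wt% observation matrix (columns Mg, O,
#'   P, C, Ca).
#' @export
make_wt_dataset <- function(params, noise_sd = 0.05, seed = NULL, day = 28,
                            noise_model = c("relative", "additive"),
                            config = NULL) {
  noise_model <- match.arg(noise_model)
  sp <- model_parameter_space(2)
  params <- params[sp$names]
  if (any(is.na(params)) || !space_contains(sp, matrix(params, 1)))
    stop("true parameters outside the model-2 testing ranges", call. = FALSE)
  cfg <- config %||% precipitation_config(k_deg = params[["k_deg"]],
                                          t_init = params[["t_init"]])
  cfg$k_deg <- params[["k_deg"]]; cfg$t_init <- params[["t_init"]]
  cfg$k_rxn <- unname(params[paste0("k", 1:6)])
  wt6 <- suppressWarnings(dl_composition(cfg, day = day))
  wt5 <- wt6[c("Mg", "O", "P", "C", "Ca")]
  wt5 <- 100 * wt5 / sum(wt5)
  noisy <- with_seed(seed, apply_noise(wt5, noise_sd, noise_model))
  noisy <- pmax(noisy, 0)
  noisy <- 100 * noisy / sum(noisy)
  obs <- time_series(day, matrix(noisy, 1, dimnames = list(NULL, names(wt5))),
                     qoi_label = "wt_percent")
  new_synth(params, obs, list(type = noise_model, sd = noise_sd), seed, 1L)
}

#' Synthetic volume-loss dataset (model 3)
#'
#' @param D_Mg Ground-truth diffusion coefficient, mm2 s-1, inside the
#'   model-3 testing range.
#' @param alloy `"Mg5Gd"` or `"Mg10Gd"`.
#' @param noise_sd,seed,noise_model As in [make_mdd_dataset()].
#' @param times Observation days (default weekly + 42/56).
#' @param config Optional [diffusion_config()] template.
#' @return A `mguq_synth` whose observations are VL percentages clipped to
#'   `[0, 100]`.
#' @export
make_vl_dataset <- function(D_Mg, alloy = "Mg5Gd", noise_sd = 0.05,
                            seed = NULL, times = c(7, 14, 21, 28, 42, 56),
                            noise_model = c("relative", "additive"),
                            config = NULL) {
  noise_model <- match.arg(noise_model)
  sp <- model_parameter_space(3)
  if (!space_contains(sp, matrix(D_Mg, 1)))
    stop("true D_Mg outside the model-3 testing range", call. = FALSE)
  cfg <- config %||% diffusion_config(D_Mg, alloy = alloy)
  cfg$D_Mg <- D_Mg
  vl <- simulate_volume_loss(cfg, output_times = times)
  noisy <- with_seed(seed, apply_noise(vl$values[, 1], noise_sd, noise_model))
  noisy <- pmin(pmax(noisy, 0), 100)
  new_synth(c(D_Mg = D_Mg),
            time_series(times, noisy, qoi_label = "VL_percent"),
            list(type = noise_model, sd = noise_sd), seed, 1L)
}

#' Write a synthetic dataset to CSV with a JSON sidecar
#'
#' The CSV holds the observations; the sidecar (`<path>.json`) records the
#' ground truth, noise model and seed.
#'
#' @param x A `mguq_synth` object.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_synth_dataset <- function(x, path) {
  stopifnot(inherits(x, "mguq_synth"))
  write_time_series(x$observations, path)
  jsonlite::write_json(
    list(true_params = as.list(x$true_params), noise_model = x$noise_model,
         seed = x$seed, replicates = x$replicates),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
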