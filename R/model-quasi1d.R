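# Model 1: quasi-1D moving-interface degradation of pure Mg in SBF.
#
# The Mg2+ release at the metal-liquid interface follows a sigmoidal rate law
# (an initial period of low degradation followed by a linear trend); the
# interface recedes with normal velocity v = (M_Mg/rho_Mg) * release rate, and
# the mean degradation depth (MDD) is the integral of that velocity, starting
# at 0 and bounded above by the length of the Mg domain.

#' Configuration for the quasi-1D pure-Mg degradation model
#'
#' @param k_deg Degradation rate constant, mol m-2 s-1; stored as printed in
#'   the testing ranges (negative); the solver uses its magnitude.
#' @param t_init Degradation onset time in days (the sigmoid midpoint),
#'   accounting for the initial protective MgO film.
#' @param epsilon Porosity of the degradation layer, in (0, 1].
#' @param r_initial Length of the Mg domain in m (default 0.2 mm).
#' @param l_electrolyte Length of the electrolyte domain in m (default 0.2 mm).
#' @param dl_init Initial degradation-layer thickness in m (default 10 nm).
#' @param M_Mg Molar mass of Mg, kg mol-1.
#' @param rho_Mg Density of Mg, kg m-3.
#' @param t_end Simulated horizon in days.
#' @param n_t Number of time steps.
#' @param n_x Number of spatial nodes carried by the configuration (the MDD
#'   solution depends on space only through `r_initial`).
#' @return An object of class `mguq_quasi1d_config`.
#' @examples
#' cfg <- quasi1d_config(k_deg = -2.4321e-5, t_init = 1.932)
#' mdd <- simulate_mdd(cfg)
#' @export
quasi1d_config <- function(k_deg, t_init, epsilon = 0.5,
                           r_initial = 2e-4, l_electrolyte = 2e-4,
                           dl_init = 1e-8, M_Mg = 0.024305, rho_Mg = 1738,
                           t_end = 28, n_t = 400L, n_x = 50L) {
  assert_num(k_deg); assert_num(t_init, lower = 0)
  assert_num(epsilon, lower = 1e-12, upper = 1)
  assert_num(r_initial, lower = 1e-12)
  assert_num(l_electrolyte, lower = 0)
  assert_num(dl_init, lower = 0, upper = r_initial)
  assert_num(M_Mg, lower = 1e-6); assert_num(rho_Mg, lower = 1e-6)
  assert_num(t_end, lower = 1e-9)
  assert_num(n_t, lower = 2); assert_num(n_x, lower = 2)
  structure(list(k_deg = k_deg, t_init = t_init, epsilon = epsilon,
                 r_initial = r_initial, l_electrolyte = l_electrolyte,
                 dl_init = dl_init, M_Mg = M_Mg, rho_Mg = rho_Mg,
                 t_end = t_end, n_t = as.integer(n_t), n_x = as.integer(n_x)),
            class = "mguq_quasi1d_config")
}

#' Effective Mg2+ release rate at the metal interface
#'
#' Sigmoidal rate law `epsilon * k_deg / (1 + exp(-(t - t_init)))`: the rate
#' rises smoothly from near zero before `t_init` to the asymptote
#' `epsilon * k_deg` once the protective film has dissolved.
#'
#' @param t Time in days (vectorised).
#' @param epsilon Degradation-layer porosity in (0, 1].
#' @param k_deg Degradation rate constant, mol m-2 s-1.
#' @param t_init Onset time in days.
#' @return Release rate, same sign convention as `k_deg`.
#' @examples
#' release_rate(5 + 1.932, epsilon = 0.5, k_deg = -2.4321e-5, t_init = 1.932)
#' @export
release_rate <- function(t, epsilon, k_deg, t_init) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and nonnegative", call. = FALSE)
  assert_num(epsilon, lower = 1e-12, upper = 1)
  assert_num(k_deg); assert_num(t_init, lower = 0)
  epsilon * k_deg / (1 + exp(-(t - t_init)))
}

#' Simulate the mean degradation depth (model 1)
#'
#' Integrates the interface velocity
#' `v = (M_Mg / rho_Mg) * |release_rate(t)|` by the trapezoidal rule on the
#' configured time grid. MDD starts at 0, is monotone nondecreasing, and is
#' capped at `r_initial`: if the Mg domain is consumed before `t_end` the
#' trajectory is truncated at the cap and flagged with a warning and the
#' `truncated` attribute.
#'
#' @param config A [quasi1d_config()].
#' @return A [time_series()] of MDD in micrometres (`qoi_label = "MDD_um"`),
#'   with attribute `truncated`.
#' @export
simulate_mdd <- function(config) {
  stopifnot(inherits(config, "mguq_quasi1d_config"))
  tt <- seq(0, config$t_end, length.out = config$n_t + 1L)
  # velocity in m/day: |k_deg| [mol m-2 s-1] * 86400 * M/rho [m3 mol-1]
  v <- config$M_Mg / config$rho_Mg * 86400 *
    abs(release_rate(tt, config$epsilon, config$k_deg, config$t_init))
  dt <- diff(tt)
  mdd <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * dt))
  truncated <- FALSE
  cap <- config$r_initial
  if (any(mdd > cap)) {
    truncated <- TRUE
    warning("Mg domain fully consumed before t_end; MDD truncated at r_initial",
            call. = FALSE)
    mdd <- pmin(mdd, cap)
  }
  out <- time_series(tt, mdd * 1e6, qoi_label = "MDD_um")
  attr(out, "truncated") <- truncated
  out
}
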