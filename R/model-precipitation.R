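# Model 2: transport-reaction model of precipitate formation in the porous
# degradation layer (DL) on the Mg surface.
#
# Six dissolved species (Mg2+, OH-, H+, HCO3-, Ca2+, HPO4 2-) diffuse on a 1D
# grid spanning the DL and the electrolyte; an optional migration term closes
# the electric field with a null-current approximation. Mg2+ (and 2 OH- per
# Mg, from the cathodic water reduction) enter at the metal boundary at the
# sigmoidal release rate of model 1. Six precipitation reactions (brucite,
# magnesite, nesquehonite, portlandite, calcite, hydroxyapatite) run only
# inside the DL, each with rate epsilon * k_l * (K_eq,l - c_i * c_j).

mguq_species <- function() {
  data.frame(
    name = c("Mg", "OH", "H", "HCO3", "Ca", "HPO4"),
    z = c(2L, -1L, 1L, -1L, 2L, -2L),
    # free-solution diffusion coefficients, m2 s-1 (infinite-dilution values)
    D = c(7.06e-10, 5.27e-9, 9.31e-9, 1.18e-9, 7.92e-10, 7.60e-10),
    stringsAsFactors = FALSE)
}

# default SBF-like initial concentrations for the tracked species, mol m-3
mguq_sbf_c0 <- function() {
  c(Mg = 1.5, OH = 2.5e-4, H = 4.0e-5, HCO3 = 4.2, Ca = 2.5, HPO4 = 1.0)
}

# reaction table: reacting pair, consumption stoichiometry, H+ produced,
# and elemental composition (mol of C, Ca, P, H, O, Mg per formula unit)
mguq_reactions <- function() {
  list(
    list(name = "brucite",        pair = c("Mg", "OH"),   nu = c(Mg = 1, OH = 2),
         h_prod = 0, elem = c(C = 0, Ca = 0, P = 0, H = 2, O = 2,  Mg = 1)),
    list(name = "magnesite",      pair = c("Mg", "HCO3"), nu = c(Mg = 1, HCO3 = 1),
         h_prod = 1, elem = c(C = 1, Ca = 0, P = 0, H = 0, O = 3,  Mg = 1)),
    list(name = "nesquehonite",   pair = c("Mg", "HCO3"), nu = c(Mg = 1, HCO3 = 1),
         h_prod = 1, elem = c(C = 1, Ca = 0, P = 0, H = 6, O = 6,  Mg = 1)),
    list(name = "portlandite",    pair = c("Ca", "OH"),   nu = c(Ca = 1, OH = 2),
         h_prod = 0, elem = c(C = 0, Ca = 1, P = 0, H = 2, O = 2,  Mg = 0)),
    list(name = "calcite",        pair = c("Ca", "HCO3"), nu = c(Ca = 1, HCO3 = 1),
         h_prod = 1, elem = c(C = 1, Ca = 1, P = 0, H = 0, O = 3,  Mg = 0)),
    list(name = "hydroxyapatite", pair = c("Ca", "HPO4"), nu = c(Ca = 5, HPO4 = 3, OH = 4),
         h_prod = 0, elem = c(C = 0, Ca = 5, P = 3, H = 1, O = 13, Mg = 0)))
}

mguq_atomic_mass <- c(C = 12.011, Ca = 40.078, P = 30.974,
                      H = 1.008, O = 15.999, Mg = 24.305)

#' Configuration for the precipitation model (model 2)
#'
#' @param k_deg,t_init Interface source-term kinetics, as in
#'   [quasi1d_config()].
#' @param k_rxn Named or positional numeric vector of the six backward
#'   reaction constants `k1`..`k6` (brucite, magnesite, nesquehonite,
#'   portlandite, calcite, hydroxyapatite), signed as printed in the testing
#'   ranges: a negative `k_l` makes the precipitate grow under supersaturation
#'   (`c_i * c_j > K_eq,l`).
#' @param K_eq Equilibrium constants of the six reactions, (mol m-3)^2. The
#'   shipped defaults are documented placeholders for an SBF-like medium and
#'   are fully overridable; no published values exist for this rate form.
#' @param epsilon DL porosity in (0, 1].
#' @param c0 Named initial concentrations (mol m-3) for the six species.
#' @param species Species table (name, charge `z`, free-solution diffusion
#'   coefficient `D` in m2 s-1); defaults to [mguq_species()] values.
#' @param D_dl Effective diffusion coefficient inside the porous DL, m2 s-1
#'   (default 1.4e-16).
#' @param dl_thickness DL thickness in m (static geometry).
#' @param l_electrolyte Electrolyte domain length in m.
#' @param temperature Temperature in K.
#' @param migration_enabled If `TRUE`, add the electromigration term with the
#'   electric field closed by a null-current (electroneutral flux) condition.
#' @param t_end Horizon in days.
#' @param n_x_dl,n_x_el Grid cells in the DL and electrolyte regions.
#' @param n_t Number of time steps.
#' @param n_sub Newton/Gauss-Seidel sweeps for the implicit reaction step.
#' @param r_initial Mg metal reservoir expressed as domain length, m.
#' @param rho_Mg,M_Mg Density (kg m-3) and molar mass (kg mol-1) of Mg.
#' @return An object of class `mguq_precip_config`.
#' @export
precipitation_config <- function(k_deg, t_init,
                                 k_rxn = c(k1 = -9.0245e-21, k2 = -7.0332e-9,
                                           k3 = -7.0023e-10, k4 = -1.0798e-2,
                                           k5 = -8.0037e-24, k6 = 9.001e16),
                                 K_eq = c(1e-2, 1e0, 1e1, 1e2, 1e-1, 1e-4),
                                 epsilon = 0.5, c0 = mguq_sbf_c0(),
                                 species = mguq_species(), D_dl = 1.4e-16,
                                 dl_thickness = 2e-5, l_electrolyte = 2e-4,
                                 temperature = 310.15,
                                 migration_enabled = FALSE,
                                 t_end = 28, n_x_dl = 8L, n_x_el = 24L,
                                 n_t = 1200L, n_sub = 6L, r_initial = 2e-4,
                                 rho_Mg = 1738, M_Mg = 0.024305) {
  assert_num(k_deg); assert_num(t_init, lower = 0)
  assert_num(k_rxn, len = 6L); assert_num(K_eq, len = 6L, lower = 0)
  assert_num(epsilon, lower = 1e-12, upper = 1)
  assert_num(D_dl, lower = 0); assert_num(dl_thickness, lower = 1e-12)
  assert_num(l_electrolyte, lower = 1e-12)
  assert_num(temperature, lower = 1)
  assert_flag(migration_enabled)
  assert_num(t_end, lower = 1e-9)
  assert_num(n_x_dl, lower = 1); assert_num(n_x_el, lower = 2)
  assert_num(n_t, lower = 2); assert_num(n_sub, lower = 1)
  if (!is.data.frame(species) || nrow(species) != 6L ||
      !all(c("name", "z", "D") %in% names(species)))
    stop("'species' must be a 6-row data frame with name, z, D", call. = FALSE)
  if (any(species$D <= 0)) stop("all D_i must be > 0", call. = FALSE)
  ref_z <- c(Mg = 2L, OH = -1L, H = 1L, HCO3 = -1L, Ca = 2L, HPO4 = -2L)
  if (!identical(as.integer(species$z), unname(ref_z[species$name])))
    stop("species charges must match their chemical identity", call. = FALSE)
  c0 <- c0[species$name]
  if (any(is.na(c0)) || any(c0 < 0))
    stop("'c0' must provide a nonnegative value for every species",
         call. = FALSE)
  structure(list(k_deg = k_deg, t_init = t_init, k_rxn = unname(k_rxn),
                 K_eq = unname(K_eq), epsilon = epsilon, c0 = c0,
                 species = species, D_dl = D_dl,
                 dl_thickness = dl_thickness, l_electrolyte = l_electrolyte,
                 temperature = temperature,
                 migration_enabled = migration_enabled, t_end = t_end,
                 n_x_dl = as.integer(n_x_dl), n_x_el = as.integer(n_x_el),
                 n_t = as.integer(n_t), n_sub = as.integer(n_sub),
                 r_initial = r_initial,
                 rho_Mg = rho_Mg, M_Mg = M_Mg),
            class = "mguq_precip_config")
}

#' Elemental weight percentages in the degradation layer
#'
#' Normalises per-element mass concentrations to percentages:
#' `wt_i = 100 * rho_i / sum(rho)`, for the elements C, Ca, P, H, O, Mg.
#'
#' @param rho_elem Nonnegative numeric vector of length 6 (order C, Ca, P, H,
#'   O, Mg unless named), not all zero.
#' @return Named vector of weight percentages summing to 100.
#' @examples
#' wt_percent(c(1, 2, 3, 4, 5, 6))
#' @export
wt_percent <- function(rho_elem) {
  assert_num(rho_elem, len = 6L, lower = 0)
  if (sum(rho_elem) == 0)
    stop("wt% undefined: all element masses are zero", call. = FALSE)
  out <- 100 * rho_elem / sum(rho_elem)
  names(out) <- names(rho_elem) %||% c("C", "Ca", "P", "H", "O", "Mg")
  out
}

# conservative variable-width 1D diffusion operator (zero-flux boundaries)
# returns the n x n matrix L with dc/dt = L %*% c
diffusion_operator <- function(dx, D_cell) {
  n <- length(dx)
  L <- matrix(0, n, n)
  if (n == 1) return(L)
  for (i in seq_len(n - 1)) {
    # harmonic-mean interface diffusivity, face between cells i and i+1
    Df <- if (D_cell[i] + D_cell[i + 1] > 0)
      2 * D_cell[i] * D_cell[i + 1] / (D_cell[i] + D_cell[i + 1]) else 0
    g <- Df / ((dx[i] + dx[i + 1]) / 2)
    L[i, i] <- L[i, i] - g / dx[i];     L[i, i + 1] <- L[i, i + 1] + g / dx[i]
    L[i + 1, i + 1] <- L[i + 1, i + 1] - g / dx[i + 1]
    L[i + 1, i] <- L[i + 1, i] + g / dx[i + 1]
  }
  L
}

#' Simulate precipitate formation in the degradation layer (model 2)
#'
#' Operator-split integration: implicit (backward-Euler) diffusion per
#' species, then an explicit precipitation step confined to the DL cells.
#' When the reactions are much faster than the time step, the demand of each
#' reaction is scaled by the availability of its reactants (at most 90% of a
#' cell's dissolved inventory is consumed per step, shared across reactions in
#' proportion to their unconstrained rates), which keeps every concentration
#' nonnegative and makes the supply-limited regime well defined.
#'
#' @param config A [precipitation_config()].
#' @param output_times Days at which the wt% trajectory is recorded (default:
#'   daily).
#' @return A list with elements `wt` (a [time_series()] of elemental wt%,
#'   columns C, Ca, P, H, O, Mg; rows are `NA` while no solid mass exists),
#'   `dissolved` (final concentration profile matrix, cells x species),
#'   `precipitates` (final DL profile matrix, DL cells x reactions),
#'   `grid` (cell widths and region index), and `audit` (Mg mole balance and
#'   H2 tally).
#' @export
simulate_precipitation <- function(config,
                                   output_times = seq(0, config$t_end)) {
  stopifnot(inherits(config, "mguq_precip_config"))
  sp <- config$species
  rx <- mguq_reactions()
  n_dl <- config$n_x_dl; n_el <- config$n_x_el
  n <- n_dl + n_el
  dx <- c(rep(config$dl_thickness / n_dl, n_dl),
          rep(config$l_electrolyte / n_el, n_el))
  in_dl <- seq_len(n_dl)

  dt <- days_to_seconds(config$t_end) / config$n_t
  tt_days <- seq(0, config$t_end, length.out = config$n_t + 1L)

  # per-species implicit diffusion propagators (effective D inside the DL)
  prop <- lapply(seq_len(6L), function(s) {
    D_cell <- c(rep(config$D_dl, n_dl), rep(sp$D[s], n_el))
    solve(diag(n) - dt * diffusion_operator(dx, D_cell))
  })

  C <- matrix(rep(config$c0, each = n), n, 6L,
              dimnames = list(NULL, sp$name))
  P <- matrix(0, n_dl, 6L,
              dimnames = list(NULL, vapply(rx, `[[`, "", "name")))

  metal <- config$r_initial * config$rho_Mg / config$M_Mg  # mol m-2 reservoir
  mg_dissolved_total <- 0                                  # mol m-2 released
  eps <- config$epsilon
  FRT <- 96485 / (8.314 * config$temperature)

  out_wt <- matrix(NA_real_, length(output_times), 6L,
                   dimnames = list(NULL, c("C", "Ca", "P", "H", "O", "Mg")))
  record <- function(k) {
    mass <- elemental_mass(P, rx, dx[in_dl])
    if (sum(mass) > 0) out_wt[k, ] <<- wt_percent(mass)
  }
  out_idx <- 1L
  while (out_idx <= length(output_times) && output_times[out_idx] <= 0) {
    record(out_idx); out_idx <- out_idx + 1L
  }

  # precomputed integer indices and hoisted constants for the hot loop
  sp_idx <- stats::setNames(seq_len(6L), sp$name)
  rx_pre <- lapply(rx, function(r) list(
    i = sp_idx[[r$pair[1]]], j = sp_idx[[r$pair[2]]],
    nui = r$nu[[r$pair[1]]], nuj = r$nu[[r$pair[2]]],
    cons = sp_idx[names(r$nu)], nu = unname(r$nu), h_prod = r$h_prod))
  h_col <- sp_idx[["H"]]
  k_rxn <- config$k_rxn; K_eq <- config$K_eq; n_sub <- config$n_sub

  truncated <- FALSE
  for (step in seq_len(config$n_t)) {
    t_mid <- (tt_days[step] + tt_days[step + 1L]) / 2
    # --- interface source: Mg2+ and 2 OH- per Mg, while metal remains
    flux <- abs(release_rate(t_mid, eps, config$k_deg, config$t_init))
    if (metal <= 0) { flux <- 0; truncated <- TRUE }
    flux <- min(flux, metal / dt)
    C[1L, "Mg"] <- C[1L, "Mg"] + flux * dt / dx[1L]
    C[1L, "OH"] <- C[1L, "OH"] + 2 * flux * dt / dx[1L]
    metal <- metal - flux * dt
    mg_dissolved_total <- mg_dissolved_total + flux * dt

    # --- optional electromigration (null-current closure), explicit
    if (config$migration_enabled) C <- migration_step(C, sp, dx, dt, FRT,
                                                      config$D_dl, n_dl)

    # --- implicit diffusion per species
    for (s in seq_len(6L)) C[, s] <- prop[[s]] %*% C[, s]

    # --- precipitation inside the DL (semi-implicit substeps; vectorised
    # over DL cells). The linearised implicit update turns stiff reactions
    # into damped Newton steps toward their solubility equilibrium
    # c_i * c_j = K_eq, so the result is insensitive to the step size.
    delta <- matrix(0, n_dl, 6L)  # accumulated step increments
    for (sweep in seq_len(n_sub)) {
      sweep_max <- 0
      for (l in seq_len(6L)) {
        kl <- k_rxn[l]
        if (kl == 0) next
        r <- rx_pre[[l]]
        ci <- C[in_dl, r$i]; cj <- C[in_dl, r$j]
        # Newton correction for the backward-Euler residual
        # delta_l = dt * eps * k_l * (K_eq - c_i c_j)  (at end-of-step c)
        resid <- dt * eps * kl * (K_eq[l] - ci * cj) - delta[, l]
        denom <- 1 + dt * eps * abs(kl) * (r$nui * cj + r$nuj * ci)
        d <- resid / denom
        lo <- -(P[, l] + delta[, l])               # no negative solid
        w <- d < lo; d[w] <- lo[w]
        for (m in seq_along(r$cons)) {             # supply limit per species
          cap <- 0.95 * C[in_dl, r$cons[m]] / r$nu[m]
          w <- d > cap; d[w] <- cap[w]
        }
        delta[, l] <- delta[, l] + d
        for (m in seq_along(r$cons)) {
          cs <- r$cons[m]
          cc <- C[in_dl, cs] - r$nu[m] * d
          cc[cc < 0] <- 0
          C[in_dl, cs] <- cc
        }
        if (r$h_prod > 0)
          C[in_dl, h_col] <- C[in_dl, h_col] + r$h_prod * d
        sweep_max <- max(sweep_max, abs(d))
      }
      if (sweep_max < 1e-14) break
    }
    P <- P + delta

    while (out_idx <= length(output_times) &&
           output_times[out_idx] <= tt_days[step + 1L] + 1e-9) {
      record(out_idx); out_idx <- out_idx + 1L
    }
  }
  if (truncated)
    warning("Mg reservoir consumed before t_end; source switched off",
            call. = FALSE)

  mg_in_precip <- sum(P %*% vapply(rx, function(r) r$elem[["Mg"]], 0) *
                        dx[in_dl])
  mg_dissolved <- sum(C[, "Mg"] * dx)
  audit <- list(mg_released = mg_dissolved_total,
                mg_dissolved = mg_dissolved - sum(config$c0[["Mg"]] * dx),
                mg_precipitated = mg_in_precip,
                metal_remaining = metal,
                h2_evolved = h2_from_mg(mg_dissolved_total))

  list(wt = time_series(output_times, out_wt, qoi_label = "wt_percent"),
       dissolved = C, precipitates = P,
       grid = list(dx = dx, in_dl = in_dl), audit = audit,
       truncated = truncated)
}

# mass concentration (arbitrary mass units per m2, widths folded in) of each
# element held in the precipitate profile
elemental_mass <- function(P, rx, dx_dl) {
  elems <- c("C", "Ca", "P", "H", "O", "Mg")
  comp <- t(vapply(rx, function(r) r$elem[elems], numeric(6)))
  moles <- colSums(P * dx_dl)            # mol m-2 per precipitate
  drop(moles %*% comp) * mguq_atomic_mass[elems]
}

# explicit electromigration step: the electric field is closed by requiring
# zero net ionic current through every face (electroneutral flux condition)
migration_step <- function(C, sp, dx, dt, FRT, D_dl, n_dl) {
  n <- nrow(C)
  Dmat <- matrix(rep(sp$D, each = n), n, 6L)
  if (n_dl > 0) Dmat[seq_len(n_dl), ] <- D_dl
  flux <- matrix(0, n - 1L, 6L)
  for (f in seq_len(n - 1L)) {
    h <- (dx[f] + dx[f + 1L]) / 2
    cf <- (C[f, ] + C[f + 1L, ]) / 2
    Df <- 2 * Dmat[f, ] * Dmat[f + 1L, ] / (Dmat[f, ] + Dmat[f + 1L, ])
    grad <- (C[f + 1L, ] - C[f, ]) / h
    num <- sum(sp$z * Df * grad)
    den <- FRT * sum(sp$z^2 * Df * cf)
    Egrad <- if (den > 0) -num / den else 0       # dV/dx
    flux[f, ] <- -sp$z * Df * FRT * cf * Egrad    # migration-only flux
  }
  for (s in seq_len(6L)) {
    div <- c(flux[1L, s], diff(flux[, s]), -flux[n - 1L, s]) /
      dx * c(1, rep(1, n - 2L), 1)
    C[, s] <- pmax(C[, s] + dt * div, 0)
  }
  C
}

#' Elemental wt% of the degradation layer at a given day (model 2 QoI)
#'
#' Convenience wrapper running [simulate_precipitation()] and returning the
#' 6-element wt% vector at `day`.
#'
#' @param config A [precipitation_config()].
#' @param day Day at which to read off the composition (default `t_end`).
#' @return Named wt% vector (C, Ca, P, H, O, Mg).
#' @export
dl_composition <- function(config, day = config$t_end) {
  res <- simulate_precipitation(config, output_times = c(0, day))
  res$wt$values[nrow(res$wt$values), ]
}
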