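# Shared fixtures: tiny analytic test functions and cheap model configs.

unit_space <- function(d = 2) {
  parameter_space(paste0("x", seq_len(d)), rep(0, d), rep(1, d))
}

# smooth nonlinear 2D test function
smooth_fn <- function(x) sin(3 * x[1]) + cos(2 * x[2]) + x[1] * x[2]

# exact degree-2 polynomial in 2D
quad_fn <- function(x) 1 + 2 * x[1] + 3 * x[2] + 1.5 * x[1] * x[2] -
  0.7 * x[2]^2

# fast model-2 configuration for tests (very coarse)
tiny_precip_config <- function(n_t = 200L, ...) {
  precipitation_config(k_deg = -2.4321e-5, t_init = 1.932,
                       n_x_dl = 4L, n_x_el = 10L, n_t = n_t, ...)
}

tiny_diffusion_config <- function(D_Mg = 6.05e-9, ...) {
  diffusion_config(D_Mg, geometry = geom_cylinder(nr = 8L, nz = 12L),
                   n_t = 40L, ...)
}

expect_monotone_nondecreasing <- function(x, tol = 1e-9) {
  expect_true(all(diff(x) >= -tol))
}

ts_at_test <- function(ts, day) {
  stats::approx(ts$times, ts$values[, 1], xout = day)$y
}

# map unit-cube points into a physical box (test-side twin of the internal
# scaling, kept independent of package internals)
space_unscale_test <- function(space, u) {
  sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
}

space_contains_test <- function(space, x) {
  all(x >= space$lower & x <= space$upper)
}
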