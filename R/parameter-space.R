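# Uncertain-parameter spaces: named uniform boxes in physical units.

#' Define a space of uniformly distributed uncertain parameters
#'
#' All uncertain parameters of the degradation models are treated as
#' independent and uniformly distributed within their testing ranges.
#'
#' @param names Character vector of unique parameter names.
#' @param lower,upper Numeric vectors of bounds, `lower < upper` elementwise.
#' @return An object of class `mguq_space`.
#' @examples
#' parameter_space(c("k_deg", "t_init"), c(-1e-4, 0), c(-1e-9, 3))
#' @export
parameter_space <- function(names, lower, upper) {
  if (!is.character(names) || anyDuplicated(names))
    stop("parameter names must be unique character strings", call. = FALSE)
  d <- length(names)
  assert_num(lower, len = d)
  assert_num(upper, len = d)
  if (any(lower >= upper))
    stop("each lower bound must be strictly below its upper bound",
         call. = FALSE)
  structure(list(names = names, lower = lower, upper = upper, dim = d),
            class = "mguq_space")
}

#' @export
print.mguq_space <- function(x, ...) {
  cat(sprintf("<mguq_space> %d uniform parameter(s)\n", x$dim))
  for (i in seq_len(x$dim))
    cat(sprintf("  %-8s U[%g, %g]\n", x$names[i], x$lower[i], x$upper[i]))
  invisible(x)
}

# map a unit-cube matrix to physical units and back
space_unscale <- function(space, u) {
  u <- as.matrix(u)
  sweep(sweep(u, 2, space$upper - space$lower, `*`), 2, space$lower, `+`)
}
space_scale <- function(space, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, space$lower, `-`), 2, space$upper - space$lower, `/`)
}
space_contains <- function(space, x) {
  x <- as.matrix(x)
  all(sweep(x, 2, space$lower, `>=`) & sweep(x, 2, space$upper, `<=`))
}

#' Testing ranges of the uncertain parameters for each degradation model
#'
#' Returns the published testing ranges used to build the parametric space:
#' model 1 has the degradation rate constant `k_deg` (mol m-2 s-1) and the
#' degradation onset `t_init` (days); model 2 adds the six backward reaction
#' constants `k1`..`k6` of the precipitation reactions (brucite, magnesite,
#' nesquehonite, portlandite, calcite, hydroxyapatite); model 3 has the single
#' diffusion coefficient `D_Mg` (mm2 s-1) of Mg2+ ions.
#'
#' @param model Integer 1, 2 or 3.
#' @return A [parameter_space()].
#' @export
model_parameter_space <- function(model) {
  model <- as.integer(model)
  switch(as.character(model),
    "1" = parameter_space(c("k_deg", "t_init"),
                          lower = c(-1e-4, 0), upper = c(-1e-9, 3)),
    "2" = parameter_space(
      c("k_deg", "t_init", "k1", "k2", "k3", "k4", "k5", "k6"),
      lower = c(-1e-4, 0, -1e-19, -1e-5, -1e-5, -1e-1, -1e-19, -1e15),
      upper = c(-1e-9, 3, -1e-23, -1e-12, -1e-12, -1e-12, -1e-25, 1e20)),
    "3" = parameter_space("D_Mg", lower = 1e-12, upper = 1e-4),
    stop("'model' must be 1, 2 or 3", call. = FALSE))
}
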