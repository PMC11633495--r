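# Forward UQ on fitted surrogates: uncertainty propagation and
# surrogate-based parameter calibration.

#' Propagate input uncertainty through a model or surrogate
#'
#' Draws a Latin hypercube sample of the uniform input space, evaluates the
#' model, and summarises the output distribution.
#'
#' @param model Fitted surrogate (`mguq_pce` / `mguq_kriging` / `mguq_pck`)
#'   or a function of a named parameter vector (or input matrix).
#' @param space A [parameter_space()].
#' @param n Sample size.
#' @param seed Seed for the input sample.
#' @return Object of class `mguq_propagation`: `mean`, `variance`, `sd`,
#'   `quantiles` (2.5/25/50/75/97.5%), `n`, `seed`, and the evaluated
#'   `samples`.
#' @export
propagate <- function(model, space, n = 1000L, seed = NULL) {
  stopifnot(inherits(space, "mguq_space"))
  assert_num(n, lower = 2)
  f <- as_model_function(model, space)
  X <- sample_one_shot(space, as.integer(n), "lhs", seed = seed)$points
  y <- f(X)
  bad <- !is.finite(y)
  if (mean(bad) > 0.1)
    stop(sprintf("model failure rate %.0f%% exceeds 10%%", 100 * mean(bad)),
         call. = FALSE)
  y <- y[!bad]
  qs <- stats::quantile(y, c(0.025, 0.25, 0.5, 0.75, 0.975), names = TRUE)
  structure(list(mean = mean(y), variance = stats::var(y), sd = stats::sd(y),
                 quantiles = qs, n = as.integer(n), n_failed = sum(bad),
                 seed = seed, samples = y),
            class = "mguq_propagation")
}

#' @export
print.mguq_propagation <- function(x, ...) {
  cat(sprintf("<mguq_propagation> n = %d: mean = %.4g, sd = %.4g\n",
              x$n, x$mean, x$sd))
  print(signif(x$quantiles, 4))
  invisible(x)
}

#' Surrogate-based parameter calibration
#'
#' Estimates the degradation-model parameters that best reproduce observed
#' data by minimising the NRMSE between predictions and observations over
#' the bounded uniform space: a seeded global LHS screen followed by
#' Nelder-Mead refinement (out-of-bounds proposals are clamped to the box).
#'
#' @param predict_fn Function mapping a named parameter vector to predictions
#'   aligned with `observed` (typically built from per-time surrogates via
#'   [time_surrogate_predictor()], or a simulator wrapper).
#' @param observed Observations: a [time_series()] or plain numeric vector.
#' @param space A [parameter_space()].
#' @param n_screen LHS screening size (default 1000).
#' @param seed Seed for the screen.
#' @return Object of class `mguq_calibration`: `par` (named optimum),
#'   `objective` (NRMSE at the optimum), `trace` (screen + refinement
#'   objective values), `n_eval`.
#' @export
calibrate <- function(predict_fn, observed, space, n_screen = 1000L,
                      seed = NULL) {
  stopifnot(inherits(space, "mguq_space"))
  y_obs <- if (inherits(observed, "mguq_ts")) as.numeric(observed$values)
           else as.numeric(observed)
  obj_of <- function(theta) {
    theta <- pmin(pmax(theta, space$lower), space$upper)
    names(theta) <- space$names
    pred <- try(as.numeric(predict_fn(theta)), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred))) return(Inf)
    nrmse(pred, y_obs)
  }
  Xs <- sample_one_shot(space, as.integer(n_screen), "lhs", seed = seed)$points
  vals <- apply(Xs, 1, obj_of)
  if (all(!is.finite(vals)))
    stop("calibration objective not finite anywhere on the screen",
         call. = FALSE)
  best_i <- which.min(vals)
  x0 <- Xs[best_i, ]
  if (space$dim == 1L) {
    # derivative-free 1-D refinement: golden-section/Brent on the bracket
    # around the best evaluated point (includes both bounds, so boundary
    # layers below the smallest screened point are still reachable)
    w <- space$upper - space$lower
    pts <- sort(unique(c(0, 1, (Xs[, 1] - space$lower) / w)))
    pv <- vapply(pts, function(u) obj_of(space$lower + u * w), numeric(1))
    i <- which.min(pv)
    br <- c(pts[max(i - 1L, 1L)], pts[min(i + 1L, length(pts))])
    op0 <- stats::optimize(function(u) obj_of(space$lower + u * w),
                           lower = br[1], upper = br[2], tol = 1e-10)
    op <- list(par = space$lower + op0$minimum * w, value = op0$objective,
               counts = c("function" = NA_integer_))
    if (pv[i] < op$value) op <- list(par = space$lower + pts[i] * w,
                                     value = pv[i],
                                     counts = c("function" = NA_integer_))
    par <- op$par
  } else {
    # Nelder-Mead in unit coordinates for comparable step sizes
    to_unit <- function(x) (x - space$lower) / (space$upper - space$lower)
    from_unit <- function(u) space$lower + pmin(pmax(u, 0), 1) *
      (space$upper - space$lower)
    op <- stats::optim(to_unit(x0), function(u) obj_of(from_unit(u)),
                       method = "Nelder-Mead",
                       control = list(maxit = 500, reltol = 1e-10))
    par <- from_unit(op$par)
  }
  if (op$value > vals[best_i] + 1e-15) { par <- x0; op$value <- vals[best_i] }
  names(par) <- space$names
  structure(list(par = par, objective = op$value,
                 trace = list(screen_best = min(vals),
                              screen_values = vals,
                              refined = op$value),
                 n_eval = as.integer(sum(c(n_screen, op$counts[["function"]]),
                                         na.rm = TRUE)),
                 seed = seed),
            class = "mguq_calibration")
}

#' @export
print.mguq_calibration <- function(x, ...) {
  cat(sprintf("<mguq_calibration> NRMSE = %.4g at\n", x$objective))
  print(signif(x$par, 5))
  invisible(x)
}

#' Fit one surrogate per output time point
#'
#' Time-resolved quantities of interest are handled by fitting an independent
#' surrogate for each column of the response matrix (one output time point,
#' or one element of a composition vector).
#'
#' @param X Design matrix (physical units).
#' @param Y_mat Response matrix, one column per time point / component.
#' @param space A [parameter_space()].
#' @param method `"kriging"`, `"pce"`, or `"pck"`.
#' @param seed Seed forwarded to the Kriging optimiser.
#' @param ... Extra arguments for the fitting function.
#' @return List of fitted surrogates, one per column (named by column).
#' @export
fit_time_surrogates <- function(X, Y_mat, space, method = c("kriging", "pce",
                                                            "pck"),
                                seed = NULL, ...) {
  method <- match.arg(method)
  Y_mat <- as.matrix(Y_mat)
  out <- lapply(seq_len(ncol(Y_mat)), function(j) {
    switch(method,
           kriging = fit_kriging(X, Y_mat[, j], space = space, seed = seed,
                                 ...),
           pce = fit_pce(X, Y_mat[, j], space = space, ...),
           pck = fit_pck(X, Y_mat[, j], space = space, seed = seed, ...))
  })
  names(out) <- colnames(Y_mat)
  out
}

#' Predictor over a list of per-time surrogates
#'
#' @param models List of fitted surrogates (from [fit_time_surrogates()]).
#' @return Function mapping a named parameter vector to the vector of
#'   per-time predictions.
#' @export
time_surrogate_predictor <- function(models) {
  function(theta) {
    M <- matrix(theta, 1)
    vapply(models, function(m) {
      p <- stats::predict(m, M)
      as.numeric(if (is.list(p)) p$mean else p)
    }, numeric(1))
  }
}
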