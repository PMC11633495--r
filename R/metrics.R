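# Surrogate validation metrics: normalised leave-one-out error (the
# adaptive-sampling stopping statistic) and NRMSE against reference data.

#' Normalised leave-one-out (or k-fold) cross-validation error
#'
#' `eps_LOO = mean((M(x_i) - M_(-i)(x_i))^2) / Var(Y)`. For a fitted PCE the
#' closed form uses the hat matrix; for fitted Kriging/PCK the closed form
#' comes from the bordered correlation system at fixed hyperparameters. For a
#' surrogate *factory* (a function `f(X, Y)` returning a fitted model with a
#' `predict` method) the error is computed by brute-force refits, optionally
#' in `k` folds (`k = n` is exactly leave-one-out).
#'
#' @param object Fitted `mguq_pce` / `mguq_kriging` / `mguq_pck` model, or a
#'   factory function.
#' @param X,Y Training data; required for the factory path.
#' @param k Number of folds for the factory path (default `n`, i.e. LOO).
#' @return Nonnegative scalar error.
#' @export
eps_loo <- function(object, X = NULL, Y = NULL, k = NULL) {
  if (inherits(object, "mguq_pce")) return(object$eps_loo)
  if (inherits(object, "mguq_kriging")) return(kriging_loo_eps(object))
  if (inherits(object, "mguq_pck")) return(kriging_loo_eps(object$kriging))
  if (!is.function(object))
    stop("'object' must be a fitted surrogate or a factory function",
         call. = FALSE)
  X <- as.matrix(X); Y <- as.numeric(Y)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 points for cross-validation",
                  call. = FALSE)
  vy <- stats::var(Y)
  if (vy == 0) {
    warning("Var(Y) = 0; eps_loo defined as 0", call. = FALSE)
    return(0)
  }
  k <- as.integer(k %||% n)
  folds <- rep(seq_len(k), length.out = n)[order(seq_len(n))]
  err2 <- numeric(0)
  for (f in seq_len(k)) {
    hold <- which(folds == f)
    fit <- object(X[-hold, , drop = FALSE], Y[-hold])
    pred <- stats::predict(fit, X[hold, , drop = FALSE])
    if (is.list(pred)) pred <- pred$mean
    err2 <- c(err2, (pred - Y[hold])^2)
  }
  mean(err2) / vy
}

#' Normalised root mean square error
#'
#' `sqrt(mean((y_ref - pred)^2)) / (max(y_ref) - min(y_ref))`, the
#' performance metric used to compare surrogate predictions with reference
#' (experimental) data.
#'
#' @param pred Predictions.
#' @param y_ref Reference values (must not be constant).
#' @return Nonnegative scalar.
#' @examples
#' nrmse(c(0, 1, 1), c(0, 1, 2))
#' @export
nrmse <- function(pred, y_ref) {
  if (length(pred) != length(y_ref) || length(y_ref) < 1)
    stop("'pred' and 'y_ref' must have equal positive length", call. = FALSE)
  rng <- max(y_ref) - min(y_ref)
  if (rng <= 0) stop("'y_ref' is constant; NRMSE undefined", call. = FALSE)
  sqrt(mean((y_ref - pred)^2)) / rng
}
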