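# Kriging (Gaussian-process) surrogate: anisotropic Matern 5/2 correlation,
# trend either constant (ordinary Kriging) or a PCE basis (universal
# Kriging / PC-Kriging), lengthscales by multi-start maximum likelihood with
# beta and sigma^2 profiled out in closed form.

#' Matern 5/2 correlation function
#'
#' `(1 + sqrt(5) r / theta + 5/3 (r/theta)^2) * exp(-sqrt(5) r / theta)`.
#'
#' @param r Nonnegative distances.
#' @param theta Positive lengthscale.
#' @return Correlation values in (0, 1].
#' @examples
#' matern52(0, 1)   # 1
#' matern52(1, 1)   # ~0.524
#' @export
matern52 <- function(r, theta) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("'r' must be finite and nonnegative", call. = FALSE)
  assert_num(theta, lower = 1e-300)
  h <- sqrt(5) * r / theta
  (1 + h + h^2 / 3) * exp(-h)
}

# anisotropic separable Matern 5/2 correlation matrix between unit-scaled
# designs U1 (n1 x d) and U2 (n2 x d). A positive `nugget` is added where the
# two points coincide exactly, which makes the predictor re-interpolating at
# the training design despite the conditioning nugget.
corr_matrix <- function(U1, U2, theta, nugget = 0) {
  n1 <- nrow(U1); n2 <- nrow(U2)
  R <- matrix(1, n1, n2)
  same <- matrix(TRUE, n1, n2)
  for (j in seq_len(ncol(U1))) {
    r <- abs(outer(U1[, j], U2[, j], `-`))
    R <- R * matern52(r, theta[j])
    if (nugget > 0) same <- same & (r == 0)
  }
  if (nugget > 0) R <- R + nugget * same
  R
}

# trend basis matrix at unit-scaled inputs (constant or PCE basis)
trend_matrix <- function(trend, U, lower, upper) {
  if (identical(trend$type, "constant")) {
    matrix(1, nrow(U), 1)
  } else if (identical(trend$type, "pce")) {
    X <- space_unscale(parameter_space(paste0("x", seq_len(ncol(U))),
                                       lower, upper), U)
    Upce <- pce_scale(X, trend$pce$lower, trend$pce$upper)
    pce_basis_matrix(Upce, trend$pce$index_set)
  } else stop("unknown trend type", call. = FALSE)
}

# profiled negative log-likelihood pieces for fixed theta
krig_profile <- function(U, Y, Fm, theta, nugget) {
  n <- nrow(U)
  R <- corr_matrix(U, U, theta)
  diag(R) <- diag(R) + nugget
  L <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  Ri_y <- backsolve(L, forwardsolve(t(L), Y))
  Ri_F <- backsolve(L, forwardsolve(t(L), Fm))
  FtRiF <- crossprod(Fm, Ri_F)
  beta <- tryCatch(solve(FtRiF, crossprod(Fm, Ri_y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  res <- Y - Fm %*% beta
  Ri_res <- backsolve(L, forwardsolve(t(L), res))
  sigma2 <- max(as.numeric(crossprod(res, Ri_res)) / n, 1e-300)
  nll <- n * log(sigma2) + 2 * sum(log(diag(L)))
  list(nll = nll, beta = as.numeric(beta), sigma2 = sigma2, L = L,
       alpha = as.numeric(Ri_res), R = R)
}

#' Fit a Kriging surrogate
#'
#' Inputs are scaled to the unit cube; anisotropic Matern 5/2 lengthscales
#' are estimated by maximum likelihood (multi-start bounded quasi-Newton on
#' log-lengthscales, seeded) with trend coefficients and process variance
#' profiled out in closed form. The model interpolates the training data up
#' to the nugget used for conditioning (escalated from 1e-10 to 1e-6 if the
#' correlation matrix is numerically singular).
#'
#' @param X Training inputs, n x d (physical units), at least 2 distinct rows.
#' @param Y Training responses.
#' @param space Optional [parameter_space()] for unit scaling (default: data
#'   range).
#' @param trend `"constant"` (ordinary Kriging) or a fitted [fit_pce()] model
#'   whose basis becomes the universal-Kriging trend.
#' @param theta Optional fixed lengthscales (unit-cube units); skips the
#'   likelihood optimisation.
#' @param nugget Initial nugget for conditioning.
#' @param n_starts Number of multi-start points for the optimiser.
#' @param seed Seed for the multi-start draws.
#' @return Object of class `mguq_kriging` with hyperparameters, Cholesky
#'   factor, trend information and `eps_loo` (closed-form leave-one-out).
#' @export
fit_kriging <- function(X, Y, space = NULL, trend = "constant", theta = NULL,
                        nugget = 1e-10, n_starts = 5L, seed = NULL) {
  X <- as.matrix(X); Y <- as.numeric(Y)
  n <- nrow(X); d <- ncol(X)
  if (length(Y) != n) stop("X and Y sizes differ", call. = FALSE)
  if (nrow(unique(round(X, 12))) < 2)
    stop("degenerate design: need at least 2 distinct training points",
         call. = FALSE)
  if (is.null(space)) {
    lower <- apply(X, 2, min); upper <- apply(X, 2, max)
    upper[upper <= lower] <- lower[upper <= lower] + 1
  } else { lower <- space$lower; upper <- space$upper }
  sp <- parameter_space(paste0("x", seq_len(d)), lower, upper)
  U <- space_scale(sp, X)
  trend <- if (identical(trend, "constant")) list(type = "constant")
           else if (inherits(trend, "mguq_pce")) list(type = "pce", pce = trend)
           else if (is.list(trend)) trend
           else stop("unsupported trend", call. = FALSE)
  Fm <- trend_matrix(trend, U, lower, upper)
  if (ncol(Fm) >= n)
    stop("trend basis must have fewer terms than training points",
         call. = FALSE)

  lb <- log(0.05); ub <- log(20)
  obj <- function(lt, ng) {
    pr <- krig_profile(U, Y, Fm, exp(lt), ng)
    if (is.null(pr) || !is.finite(pr$nll)) 1e10 else pr$nll
  }
  fit_with_nugget <- function(ng) {
    if (!is.null(theta)) return(list(theta = theta, nugget = ng))
    starts <- with_seed(seed, rbind(rep(log(1), d),
      matrix(stats::runif((n_starts - 1L) * d, lb, ub), n_starts - 1L, d)))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      op <- try(stats::optim(starts[s, ], obj, ng = ng, method = "L-BFGS-B",
                             lower = rep(lb, d), upper = rep(ub, d)),
                silent = TRUE)
      if (inherits(op, "try-error")) next
      if (is.null(best) || op$value < best$value) best <- op
    }
    if (is.null(best)) return(NULL)
    list(theta = exp(best$par), nugget = ng)
  }

  pr <- NULL; used <- NULL
  for (ng in unique(c(nugget, 1e-8, 1e-6))) {
    cand <- fit_with_nugget(ng)
    if (is.null(cand)) next
    pr <- krig_profile(U, Y, Fm, cand$theta, cand$nugget)
    if (!is.null(pr)) { used <- cand; break }
  }
  if (is.null(pr))
    stop("Kriging correlation matrix singular even after nugget escalation",
         call. = FALSE)

  obj <- structure(list(
    U = U, Y = Y, Fm = Fm, theta = used$theta, nugget = used$nugget,
    beta = pr$beta, sigma2 = pr$sigma2, L = pr$L, alpha = pr$alpha,
    trend = trend, lower = lower, upper = upper, n_train = n,
    kernel = "matern52"), class = "mguq_kriging")
  obj$eps_loo <- kriging_loo_eps(obj)
  obj
}

# closed-form leave-one-out residuals for (universal) Kriging at fixed
# hyperparameters, via the bordered system [[R, F], [F', 0]]
kriging_loo_residuals <- function(model) {
  n <- model$n_train
  p <- ncol(model$Fm)
  R <- corr_matrix(model$U, model$U, model$theta)
  diag(R) <- diag(R) + model$nugget
  C <- rbind(cbind(R, model$Fm), cbind(t(model$Fm), matrix(0, p, p)))
  B <- solve(C)
  lam <- B %*% c(model$Y, rep(0, p))
  as.numeric(lam[seq_len(n)] / diag(B)[seq_len(n)])
}

kriging_loo_eps <- function(model) {
  vy <- stats::var(model$Y)
  if (vy == 0) {
    warning("Var(Y) = 0; eps_loo defined as 0", call. = FALSE)
    return(0)
  }
  mean(kriging_loo_residuals(model)^2) / vy
}

#' @export
predict.mguq_kriging <- function(object, newdata, se = FALSE, ...) {
  Xn <- as.matrix(newdata)
  if (is.null(dim(newdata)) &&
      length(newdata) == length(object$theta)) Xn <- matrix(newdata, 1)
  sp <- parameter_space(paste0("x", seq_len(ncol(Xn))),
                        object$lower, object$upper)
  Un <- space_scale(sp, Xn)
  r <- corr_matrix(object$U, Un, object$theta, nugget = object$nugget)  # n x m
  Fn <- trend_matrix(object$trend, Un, object$lower, object$upper)
  mean <- as.numeric(Fn %*% object$beta + crossprod(r, object$alpha))
  if (!se) return(mean)
  L <- object$L
  Ri_r <- backsolve(L, forwardsolve(t(L), r))
  Ri_F <- backsolve(L, forwardsolve(t(L), object$Fm))
  FtRiF <- crossprod(object$Fm, Ri_F)
  u <- t(Fn) - crossprod(object$Fm, Ri_r)           # p x m
  var_part <- 1 + object$nugget - colSums(r * Ri_r) +
    colSums(u * solve(FtRiF, u))
  s2 <- pmax(object$sigma2 * var_part, 0)
  list(mean = mean, se = sqrt(s2))
}

#' @export
print.mguq_kriging <- function(x, ...) {
  cat(sprintf(
    "<mguq_kriging> n_train = %d, trend = %s, sigma2 = %.3g, eps_LOO = %.3g\n",
    x$n_train, x$trend$type, x$sigma2, x$eps_loo))
  cat("  theta:", signif(x$theta, 4), "\n")
  invisible(x)
}

#' Fit a polynomial chaos Kriging (PCK) surrogate
#'
#' Sequential construction: the optimal sparse PCE basis is selected first
#' (by leave-one-out error over the candidate degrees), then a universal
#' Kriging model is fitted with that basis as its trend, capturing local
#' variation the polynomial part misses.
#'
#' @inheritParams fit_kriging
#' @param degree_range,q Passed to [fit_pce()] for the trend selection.
#' @return Object of class `mguq_pck` (also inherits the fitted Kriging
#'   interface) with fields `pce_trend` and `kriging`.
#' @export
fit_pck <- function(X, Y, space = NULL, degree_range = 1:10, q = 0.75,
                    nugget = 1e-10, n_starts = 5L, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  pce <- fit_pce(X, Y, space = space, degree_range = degree_range, q = q)
  # the Kriging stage needs strictly fewer trend terms than points; trim the
  # selected degree if the chosen basis is too rich
  while (nrow(pce$index_set) >= n && pce$degree > 0)
    pce <- fit_pce(X, Y, space = space, degree_range = 0:(pce$degree - 1),
                   q = q)
  krig <- fit_kriging(X, Y, space = space, trend = pce, nugget = nugget,
                      n_starts = n_starts, seed = seed)
  structure(list(pce_trend = pce, kriging = krig,
                 eps_loo = krig$eps_loo, n_train = n),
            class = c("mguq_pck"))
}

#' @export
predict.mguq_pck <- function(object, newdata, se = FALSE, ...) {
  stats::predict(object$kriging, newdata, se = se, ...)
}

#' @export
print.mguq_pck <- function(x, ...) {
  cat(sprintf("<mguq_pck> PCE trend degree %d (%d terms) + Kriging, eps_LOO = %.3g\n",
              x$pce_trend$degree, nrow(x$pce_trend$index_set), x$eps_loo))
  invisible(x)
}
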