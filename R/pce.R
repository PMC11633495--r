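# Sparse polynomial chaos expansion on orthonormal Legendre polynomials
# (uniform inputs scaled to [-1, 1]) with hyperbolic q-norm truncation and
# degree-adaptive least-squares fitting.

#' Hyperbolic multi-index set
#'
#' All multi-indices `alpha` with `(sum(alpha^q))^(1/q) <= p`. For `q = 1`
#' this is the total-degree set with `choose(p + n, n)` members; smaller `q`
#' prunes high-interaction terms.
#'
#' @param n_dims Number of input dimensions.
#' @param p Maximal total polynomial degree (>= 0).
#' @param q Hyperbolic norm parameter in (0, 1].
#' @return Integer matrix, one multi-index per row.
#' @examples
#' nrow(build_index_set(2, 3, 1)) # 10
#' @export
build_index_set <- function(n_dims, p, q = 1) {
  assert_num(n_dims, lower = 1); assert_num(p, lower = 0)
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q > 1)
    stop("'q' must lie in (0, 1]", call. = FALSE)
  n_dims <- as.integer(n_dims); p <- as.integer(p)
  # enumerate alpha with total degree <= p (superset of every q <= 1 set)
  rec <- function(d, budget) {
    if (d == 1L) return(matrix(0:budget, ncol = 1))
    do.call(rbind, lapply(0:budget, function(a)
      cbind(a, rec(d - 1L, budget - a), deparse.level = 0)))
  }
  idx <- rec(n_dims, p)
  qn <- rowSums(idx^q)^(1 / q)
  idx <- idx[qn <= p + 1e-12, , drop = FALSE]
  idx <- idx[order(rowSums(idx), apply(idx, 1, paste, collapse = ",")), ,
             drop = FALSE]
  dimnames(idx) <- NULL
  idx
}

# orthonormal Legendre polynomials on [-1, 1] (uniform measure), degrees
# 0..p_max, evaluated at vector u; returns length(u) x (p_max + 1) matrix
legendre_orthonormal <- function(u, p_max) {
  out <- matrix(0, length(u), p_max + 1L)
  out[, 1] <- 1
  if (p_max >= 1) out[, 2] <- u
  if (p_max >= 2) for (k in 1:(p_max - 1))
    out[, k + 2] <- ((2 * k + 1) * u * out[, k + 1] - k * out[, k]) / (k + 1)
  sweep(out, 2, sqrt(2 * (0:p_max) + 1), `*`)
}

# design matrix of multivariate basis polynomials at unit-scaled inputs
pce_basis_matrix <- function(U, index_set) {
  n <- nrow(U); d <- ncol(U)
  p_max <- max(index_set)
  uni <- lapply(seq_len(d), function(j) legendre_orthonormal(U[, j], p_max))
  Psi <- matrix(1, n, nrow(index_set))
  for (r in seq_len(nrow(index_set)))
    for (j in seq_len(d))
      if (index_set[r, j] > 0)
        Psi[, r] <- Psi[, r] * uni[[j]][, index_set[r, j] + 1L]
  Psi
}

# scale physical inputs to [-1, 1] per dimension
pce_scale <- function(X, lower, upper) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, (lower + upper) / 2, `-`), 2, (upper - lower) / 2, `/`)
}

#' Fit a polynomial chaos expansion by degree-adaptive least squares
#'
#' For each candidate degree `p`, builds the hyperbolic index set, fits the
#' expansion coefficients by least squares on the orthonormal Legendre basis,
#' and computes the normalised leave-one-out error from the hat matrix; the
#' degree with the lowest error is selected automatically. Ill-conditioned
#' designs fall back to a small ridge penalty with a warning.
#'
#' @param X Training inputs, n x d matrix (physical units).
#' @param Y Training responses, length n.
#' @param space Optional [parameter_space()] supplying the input bounds for
#'   the [-1, 1] scaling; defaults to the data range.
#' @param degree_range Candidate degrees (default 1:10); degrees whose basis
#'   exceeds the sample size are skipped.
#' @param q Hyperbolic truncation norm (default 0.75).
#' @return Object of class `mguq_pce` with coefficients, index set, scaling,
#'   selected degree and `eps_loo`.
#' @export
fit_pce <- function(X, Y, space = NULL, degree_range = 1:10, q = 0.75) {
  X <- as.matrix(X); Y <- as.numeric(Y)
  n <- nrow(X); d <- ncol(X)
  if (length(Y) != n) stop("X and Y sizes differ", call. = FALSE)
  if (is.null(space)) {
    lower <- apply(X, 2, min); upper <- apply(X, 2, max)
    upper[upper <= lower] <- lower[upper <= lower] + 1
  } else { lower <- space$lower; upper <- space$upper }
  U <- pce_scale(X, lower, upper)
  vy <- stats::var(Y)

  best <- NULL
  for (p in sort(unique(as.integer(degree_range)))) {
    idx <- build_index_set(d, p, q)
    # a saturated basis (terms == n) interpolates and makes the hat-matrix
    # leave-one-out error degenerate, so require strictly fewer terms
    if (nrow(idx) >= n && p > 0) next
    Psi <- pce_basis_matrix(U, idx)
    fit <- pce_lstsq(Psi, Y)
    eps <- if (vy > 0) mean((fit$resid / pmax(1 - fit$hat, 1e-12))^2) / vy
           else { warning("Var(Y) = 0; eps_loo defined as 0", call. = FALSE); 0 }
    if (is.null(best) || eps < best$eps) {
      best <- list(eps = eps, p = p, idx = idx, coef = fit$coef,
                   ridge = fit$ridge)
    }
  }
  if (is.null(best))
    stop("no candidate degree has a basis small enough for n_train",
         call. = FALSE)
  structure(list(coefficients = best$coef, index_set = best$idx,
                 degree = best$p, q = q, lower = lower, upper = upper,
                 eps_loo = best$eps, n_train = n, ridge = best$ridge,
                 var_y = vy),
            class = "mguq_pce")
}

# least squares with hat diagonal; ridge fallback for rank deficiency
pce_lstsq <- function(Psi, Y) {
  qr_ <- qr(Psi)
  if (qr_$rank == ncol(Psi)) {
    coef <- qr.coef(qr_, Y)
    Q <- qr.Q(qr_)
    hat <- rowSums(Q^2)
    list(coef = coef, resid = Y - Psi %*% coef, hat = hat, ridge = 0)
  } else {
    warning("ill-conditioned PCE design; ridge fallback", call. = FALSE)
    lam <- 1e-8 * mean(colSums(Psi^2))
    Ginv <- solve(crossprod(Psi) + lam * diag(ncol(Psi)))
    coef <- Ginv %*% crossprod(Psi, Y)
    H <- Psi %*% Ginv %*% t(Psi)
    list(coef = as.numeric(coef), resid = Y - Psi %*% coef,
         hat = diag(H), ridge = lam)
  }
}

#' @export
predict.mguq_pce <- function(object, newdata, ...) {
  U <- pce_scale(as.matrix(newdata), object$lower, object$upper)
  Psi <- pce_basis_matrix(U, object$index_set)
  as.numeric(Psi %*% object$coefficients)
}

#' @export
print.mguq_pce <- function(x, ...) {
  cat(sprintf(
    "<mguq_pce> degree %d (q = %g), %d basis terms, n_train = %d, eps_LOO = %.3g\n",
    x$degree, x$q, nrow(x$index_set), x$n_train, x$eps_loo))
  invisible(x)
}
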