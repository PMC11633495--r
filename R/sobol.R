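# Variance-based global sensitivity analysis: analytic Sobol indices from
# PCE coefficients, and a pick-freeze Monte Carlo estimator for black-box
# surrogates (used with Kriging, which has no analytic decomposition).

#' Analytic Sobol indices from a polynomial chaos expansion
#'
#' The orthonormal PCE coefficients decompose the response variance exactly:
#' `S_i` sums the squared coefficients of terms involving only input `i`,
#' `S_T,i` sums those of every term involving input `i`, both divided by the
#' total variance `D = sum of squared non-constant coefficients`.
#'
#' @param model A fitted [fit_pce()] model, or a [fit_pck()] model (its PCE
#'   trend carries the decomposition).
#' @return Object of class `mguq_sobol` with `first_order`, `total`,
#'   `variance` and `estimator = "analytic-pce"`.
#' @export
sobol_from_pce <- function(model) {
  if (inherits(model, "mguq_pck")) model <- model$pce_trend
  if (!inherits(model, "mguq_pce"))
    stop("'model' must be a fitted PCE or PCK", call. = FALSE)
  idx <- model$index_set
  coef2 <- as.numeric(model$coefficients)^2
  nz <- rowSums(idx) > 0
  D <- sum(coef2[nz])
  if (D == 0)
    stop("constant PCE: Sobol indices undefined (zero variance)",
         call. = FALSE)
  d <- ncol(idx)
  S <- numeric(d); ST <- numeric(d)
  for (j in seq_len(d)) {
    only_j <- idx[, j] > 0 & rowSums(idx[, -j, drop = FALSE]) == 0
    any_j <- idx[, j] > 0
    S[j] <- sum(coef2[only_j]) / D
    ST[j] <- sum(coef2[any_j]) / D
  }
  structure(list(first_order = S, total = ST, variance = D,
                 estimator = "analytic-pce", se_first = rep(0, d),
                 se_total = rep(0, d)),
            class = "mguq_sobol")
}

#' Pick-freeze Monte Carlo Sobol indices
#'
#' Saltelli-type estimator: two independent input samples A and B plus the d
#' hybrid matrices AB_i give `S_i = mean(y_B * (y_ABi - y_A)) / V` and
#' `S_T,i = mean((y_A - y_ABi)^2) / (2 V)`. Standard errors come from 200
#' bootstrap resamples of the sample indices. Small negative estimates are
#' reported as-is with their error bars.
#'
#' @param model_fn Function mapping an input matrix (or named vector) to
#'   responses; fitted surrogates are accepted directly.
#' @param space A [parameter_space()].
#' @param n Base sample size (>= 64); total evaluations are `n * (d + 2)`.
#' @param seed Seed for the input samples and the bootstrap.
#' @param n_boot Bootstrap resamples for the error bars.
#' @return Object of class `mguq_sobol` with `first_order`, `total`,
#'   `se_first`, `se_total`, `estimator = "mc-pick-freeze"`.
#' @export
sobol_mc <- function(model_fn, space, n = 1024L, seed = NULL,
                     n_boot = 200L) {
  stopifnot(inherits(space, "mguq_space"))
  assert_num(n, lower = 64)
  n <- as.integer(n)
  d <- space$dim
  f <- as_model_function(model_fn, space)
  AB <- with_seed(seed, matrix(stats::runif(2L * n * d), 2L * n, d))
  A <- space_unscale(space, AB[seq_len(n), , drop = FALSE])
  B <- space_unscale(space, AB[n + seq_len(n), , drop = FALSE])
  colnames(A) <- colnames(B) <- space$names
  yA <- f(A); yB <- f(B)
  V <- stats::var(c(yA, yB))
  if (V == 0) stop("degenerate model: zero output variance", call. = FALSE)
  yABi <- matrix(0, n, d)
  for (j in seq_len(d)) {
    M <- A; M[, j] <- B[, j]
    yABi[, j] <- f(M)
  }
  est <- function(w) {
    v <- stats::var(c(yA[w], yB[w]))
    S <- vapply(seq_len(d), function(j)
      mean(yB[w] * (yABi[w, j] - yA[w])) / v, numeric(1))
    ST <- vapply(seq_len(d), function(j)
      mean((yA[w] - yABi[w, j])^2) / (2 * v), numeric(1))
    c(S, ST)
  }
  full <- est(seq_len(n))
  boots <- with_seed(derive_seed(seed, 7L), {
    vapply(seq_len(n_boot), function(b)
      est(sample.int(n, n, replace = TRUE)), numeric(2L * d))
  })
  se <- apply(matrix(boots, nrow = 2L * d), 1, stats::sd)
  structure(list(first_order = full[seq_len(d)],
                 total = full[d + seq_len(d)],
                 se_first = se[seq_len(d)], se_total = se[d + seq_len(d)],
                 variance = V, n = n, estimator = "mc-pick-freeze"),
            class = "mguq_sobol")
}

#' @export
print.mguq_sobol <- function(x, ...) {
  cat(sprintf("<mguq_sobol> estimator: %s\n", x$estimator))
  df <- data.frame(S = signif(x$first_order, 4), S_T = signif(x$total, 4))
  print(df)
  invisible(x)
}

# coerce surrogates / row-wise functions into a matrix -> vector evaluator
as_model_function <- function(model_fn, space) {
  if (inherits(model_fn, c("mguq_pce", "mguq_kriging", "mguq_pck"))) {
    mdl <- model_fn
    return(function(M) {
      p <- stats::predict(mdl, M)
      if (is.list(p)) p$mean else p
    })
  }
  if (!is.function(model_fn)) stop("unsupported model", call. = FALSE)
  function(M) {
    M <- as.matrix(M)
    out <- try(model_fn(M), silent = TRUE)
    if (!inherits(out, "try-error") && is.numeric(out) &&
        length(out) == nrow(M)) return(as.numeric(out))
    apply(M, 1, function(r) {
      names(r) <- space$names
      as.numeric(model_fn(r))
    })
  }
}

#' Sobol indices in long-format data frame
#'
#' @param x A `mguq_sobol` object.
#' @param params Optional parameter names.
#' @param qoi,time Optional labels attached to every row.
#' @return Data frame with columns qoi, time, param, S, S_T, se_S, se_ST.
#' @export
sobol_as_df <- function(x, params = NULL, qoi = NA_character_,
                        time = NA_real_) {
  stopifnot(inherits(x, "mguq_sobol"))
  d <- length(x$first_order)
  data.frame(qoi = qoi, time = time,
             param = params %||% paste0("x", seq_len(d)),
             S = x$first_order, S_T = x$total,
             se_S = x$se_first, se_ST = x$se_total,
             estimator = x$estimator)
}
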