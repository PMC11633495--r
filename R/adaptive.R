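# Adaptive design of experiments: start from a small LHS design, enrich with
# CMM-selected points until the surrogate's leave-one-out error drops below a
# threshold, the budget is exhausted, or enrichment stops paying off.

#' Adaptive sampling for surrogate construction
#'
#' Fits a surrogate on an initial Latin hypercube design and then iterates:
#' compute the normalised leave-one-out error; stop if it is below `theta`;
#' otherwise add the point chosen by [cmm_select()] from a fresh seeded LHS
#' candidate pool, evaluate the simulator there, and refit. The loop also
#' stops at the evaluation budget or when the best error has not improved by
#' at least `patience_tol` (relative) for `patience` consecutive iterations.
#' Simulator failures reject the point, are logged, and the loop continues.
#'
#' @param model_fn Function taking a named parameter vector and returning a
#'   scalar response.
#' @param space A [parameter_space()].
#' @param surrogate_factory Function `f(X, Y)` returning a fitted surrogate
#'   exposing [eps_loo()] and `predict` (e.g. a wrapper over [fit_kriging()],
#'   [fit_pce()] or [fit_pck()]).
#' @param theta Stopping threshold on the leave-one-out error (default 1e-4).
#' @param budget Total evaluation budget `N_T` (>= `n_initial`).
#' @param n_initial Initial LHS design size; defaults to ten times the number
#'   of parameters.
#' @param patience,patience_tol Enrichment stops after `patience` consecutive
#'   iterations in which the best error improved by less than `patience_tol`
#'   (relative).
#' @param pool_size Candidate pool size per iteration (default 100 per
#'   dimension).
#' @param seed Master seed; every stage derives its own substream from it.
#' @return Object of class `mguq_adaptive`: design `X`, responses `Y`,
#'   `eps_history` (one entry per fit), `best_history` (running minimum),
#'   `surrogate` (final fit), `stop_reason`, `n_initial`, `theta`, `budget`,
#'   `n_rejected`.
#' @export
adaptive_sample <- function(model_fn, space, surrogate_factory,
                            theta = 1e-4, budget,
                            n_initial = 10L * space$dim,
                            patience = 10L, patience_tol = 0.01,
                            pool_size = 100L * space$dim, seed = NULL) {
  stopifnot(inherits(space, "mguq_space"))
  assert_num(theta, lower = 0)
  assert_num(budget, lower = 1)
  n_initial <- as.integer(n_initial)
  if (budget < n_initial)
    stop("'budget' must be at least the initial design size", call. = FALSE)

  design <- sample_one_shot(space, n_initial, "lhs",
                            seed = derive_seed(seed, 1L))
  X <- design$points
  evaluate <- function(x) {
    xx <- as.numeric(x); names(xx) <- space$names
    tryCatch(as.numeric(model_fn(xx)), error = function(e) NA_real_)
  }
  Y <- apply(X, 1, evaluate)
  ok <- is.finite(Y)
  n_rejected <- sum(!ok)
  X <- X[ok, , drop = FALSE]; Y <- Y[ok]

  eps_hist <- numeric(0)
  stop_reason <- NULL
  surrogate <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    surrogate <- surrogate_factory(X, Y)
    eps <- suppressWarnings(eps_loo(surrogate))
    eps_hist <- c(eps_hist, eps)
    best <- min(eps_hist)
    if (eps < theta) { stop_reason <- "threshold"; break }
    if (nrow(X) >= budget) { stop_reason <- "budget"; break }
    # patience: count trailing fits without >= patience_tol relative gain
    stalled <- 0L
    run_best <- eps_hist[1]
    gains <- logical(length(eps_hist) - 1L)
    if (length(eps_hist) > 1L) for (i in 2:length(eps_hist)) {
      gains[i - 1L] <- eps_hist[i] < run_best * (1 - patience_tol)
      run_best <- min(run_best, eps_hist[i])
    }
    if (length(gains) > 0) {
      tail_no_gain <- rev(cumprod(rev(!gains)))
      stalled <- sum(as.logical(tail_no_gain))
    }
    if (stalled >= patience) { stop_reason <- "patience"; break }

    pool <- sample_one_shot(space, as.integer(pool_size), "lhs",
                            seed = derive_seed(seed, 100L + iter))$points
    x_new <- cmm_select(pool, X, surrogate = surrogate, space = space)
    # never duplicate an existing design point (scaled distance 1e-12)
    ds <- space_scale(space, matrix(x_new, 1))
    if (min(colSums((t(space_scale(space, X)) - as.numeric(ds))^2)) < 1e-24) {
      n_rejected <- n_rejected + 1L
      next
    }
    y_new <- evaluate(x_new)
    if (!is.finite(y_new)) { n_rejected <- n_rejected + 1L; next }
    X <- rbind(X, x_new)
    rownames(X) <- NULL
    Y <- c(Y, y_new)
  }

  structure(list(X = X, Y = Y, eps_history = eps_hist,
                 best_history = cummin(eps_hist), surrogate = surrogate,
                 stop_reason = stop_reason, n_initial = n_initial,
                 theta = theta, budget = as.integer(budget),
                 n_rejected = n_rejected, seed = seed, space = space),
            class = "mguq_adaptive")
}

#' @export
print.mguq_adaptive <- function(x, ...) {
  cat(sprintf(
    "<mguq_adaptive> n = %d (initial %d, budget %d), eps_LOO = %.3g, stopped: %s\n",
    nrow(x$X), x$n_initial, x$budget, utils::tail(x$eps_history, 1),
    x$stop_reason))
  invisible(x)
}
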