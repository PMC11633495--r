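# Design of computer experiments: one-shot samplers (MC, LHS, Sobol, Halton)
# and the constrained min-max (CMM) selection rule used by adaptive sampling.

#' Minimum one-shot design size
#'
#' The minimum number of samples for a one-shot design is ten times the
#' number of uncertain parameters plus two (10N + 2).
#'
#' @param n_params Number of uncertain parameters (>= 1).
#' @return Integer design size.
#' @examples
#' min_one_shot_size(8) # 82
#' @export
min_one_shot_size <- function(n_params) {
  assert_num(n_params, lower = 1)
  as.integer(10 * n_params + 2)
}

# radical-inverse (van der Corput) sequence in a given base
radical_inverse <- function(idx, base) {
  out <- numeric(length(idx))
  f <- 1 / base
  k <- idx
  while (any(k > 0)) {
    out <- out + f * (k %% base)
    k <- k %/% base
    f <- f / base
  }
  out
}

halton_seq <- function(n, d, shift = NULL) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  if (d > length(primes)) stop("Halton supported up to 12 dimensions",
                               call. = FALSE)
  u <- vapply(seq_len(d), function(j) radical_inverse(seq_len(n) + 19L,
                                                      primes[j]),
              numeric(n))
  u <- matrix(u, n, d)
  if (!is.null(shift)) u <- (u + matrix(shift, n, d, byrow = TRUE)) %% 1
  u
}

# Sobol low-discrepancy sequence (gray-code construction) with primitive
# polynomials and initial direction numbers for dimensions up to 12.
sobol_seq <- function(n, d, scramble_xor = NULL) {
  if (d > 12) stop("Sobol sequence supported up to 12 dimensions",
                   call. = FALSE)
  params <- list(  # degree s, polynomial coefficient a, initial m values
    list(s = 1, a = 0, m = 1),
    list(s = 2, a = 1, m = c(1, 3)),
    list(s = 3, a = 1, m = c(1, 3, 1)),
    list(s = 3, a = 2, m = c(1, 1, 1)),
    list(s = 4, a = 1, m = c(1, 1, 3, 3)),
    list(s = 4, a = 4, m = c(1, 3, 5, 13)),
    list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
    list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
    list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)),
    list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
    list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)))
  nbits <- 31L
  U <- matrix(0, n, d)
  for (j in seq_len(d)) {
    v <- integer(nbits)
    if (j == 1L) {
      for (k in seq_len(nbits)) v[k] <- bitwShiftL(1L, nbits - k)
    } else {
      pp <- params[[j - 1L]]
      s <- pp$s
      m <- as.integer(pp$m)
      for (k in seq_len(min(s, nbits))) v[k] <- bitwShiftL(m[k], nbits - k)
      if (nbits > s) for (k in (s + 1L):nbits) {
        vk <- bitwXor(v[k - s], v[k - s] %/% bitwShiftL(1L, s))
        for (l in seq_len(s - 1L))
          if (bitwAnd(pp$a, bitwShiftL(1L, s - 1L - l)) != 0L)
            vk <- bitwXor(vk, v[k - l])
        v[k] <- vk
      }
    }
    # gray-code construction over indices 0 .. n-1 (a proper digital net)
    x <- 0L
    xs <- integer(n)
    for (i in seq_len(n)) {
      xs[i] <- x
      cbit <- 1L; ii <- i
      while (bitwAnd(ii, 1L) == 0L) { ii <- bitwShiftR(ii, 1L); cbit <- cbit + 1L }
      x <- bitwXor(x, v[cbit])
    }
    if (!is.null(scramble_xor)) xs <- bitwXor(xs, scramble_xor[j])
    U[, j] <- xs / 2^nbits
  }
  U
}

#' Generate a one-shot design
#'
#' Four one-shot sampling methods over a uniform parameter space: plain Monte
#' Carlo (`"mc"`), Latin hypercube sampling (`"lhs"`, exactly one point per
#' marginal stratum), and the Sobol and Halton low-discrepancy sequences.
#' Sequences are randomised (digital XOR scramble for Sobol, Cranley-Patterson
#' rotation for Halton) only when a seed is given, so the unseeded sequences
#' are the plain deterministic ones.
#'
#' @param space A [parameter_space()].
#' @param n Number of points (>= 1).
#' @param method One of `"mc"`, `"lhs"`, `"sobol"`, `"halton"`.
#' @param seed Optional integer seed; a fixed seed reproduces the design
#'   exactly.
#' @return An object of class `mguq_design`: list with `points` (n x d matrix
#'   in physical units, named columns), `method`, `seed`.
#' @export
sample_one_shot <- function(space, n, method = c("lhs", "mc", "sobol",
                                                 "halton"), seed = NULL) {
  stopifnot(inherits(space, "mguq_space"))
  assert_num(n, lower = 1)
  method <- match.arg(method)
  n <- as.integer(n)
  d <- space$dim
  u <- with_seed(seed, switch(method,
    mc = matrix(stats::runif(n * d), n, d),
    lhs = lhs::randomLHS(n, d),
    sobol = sobol_seq(n, d, scramble_xor = if (!is.null(seed))
      as.integer(floor(stats::runif(d) * 2^31)) else NULL),
    halton = halton_seq(n, d, shift = if (!is.null(seed))
      stats::runif(d) else NULL)))
  pts <- space_unscale(space, u)
  colnames(pts) <- space$names
  structure(list(points = pts, method = method, seed = seed,
                 space = space), class = "mguq_design")
}

#' @export
print.mguq_design <- function(x, ...) {
  cat(sprintf("<mguq_design> %d points x %d dims, method = %s\n",
              nrow(x$points), ncol(x$points), x$method))
  invisible(x)
}

#' Constrained min-max selection of the next training point
#'
#' Returns the candidate that maximises the minimum Euclidean distance (in
#' unit-scaled coordinates) to the existing design. When a surrogate with
#' predictive uncertainty is supplied (Kriging or PC-Kriging), the pool is
#' first restricted to its upper quartile of predictive variance, so new
#' points land in space-filling positions within high-uncertainty regions.
#' Ties break to the lowest candidate index; the rule is deterministic.
#'
#' @param pool Candidate matrix (physical units), one candidate per row.
#' @param design Existing design matrix (physical units).
#' @param surrogate Optional fitted surrogate providing predictive variance
#'   via `predict(..., se = TRUE)`.
#' @param space Optional [parameter_space()] used for unit scaling; defaults
#'   to the combined range of pool and design.
#' @return The selected candidate row (named numeric vector), with attribute
#'   `index` giving its position in `pool`.
#' @export
cmm_select <- function(pool, design, surrogate = NULL, space = NULL) {
  pool <- as.matrix(pool); design <- as.matrix(design)
  if (nrow(pool) == 0) stop("candidate pool is empty", call. = FALSE)
  if (is.null(space)) {
    lo <- pmin(apply(pool, 2, min), apply(design, 2, min))
    hi <- pmax(apply(pool, 2, max), apply(design, 2, max))
    hi[hi <= lo] <- lo[hi <= lo] + 1
    space <- parameter_space(paste0("x", seq_len(ncol(pool))), lo, hi)
  }
  up <- space_scale(space, pool)
  ud <- space_scale(space, design)
  keep <- seq_len(nrow(pool))
  if (!is.null(surrogate)) {
    pr <- try(stats::predict(surrogate, pool, se = TRUE), silent = TRUE)
    if (!inherits(pr, "try-error") && is.list(pr) && !is.null(pr$se) &&
        any(is.finite(pr$se))) {
      thr <- stats::quantile(pr$se, 0.75, na.rm = TRUE, names = FALSE)
      sel <- which(pr$se >= thr)
      if (length(sel) > 0) keep <- sel
    }
  }
  # min distance from each kept candidate to the design
  d2 <- vapply(keep, function(i) {
    min(colSums((t(ud) - up[i, ])^2))
  }, numeric(1))
  best <- keep[which.max(d2)]  # which.max takes the first maximum: lowest index
  out <- pool[best, ]
  names(out) <- colnames(pool)
  attr(out, "index") <- best
  out
}
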