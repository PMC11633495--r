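# JSON serialisation of fitted surrogates for exact reload.

#' Write a fitted surrogate to JSON
#'
#' Stores coefficients, hyperparameters, scaling and (for Kriging) the
#' training design at full precision; derived factors (Cholesky, Kriging
#' weights) are recomputed on reload, so the round trip reproduces
#' predictions exactly.
#'
#' @param model Fitted `mguq_pce`, `mguq_kriging` or `mguq_pck`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_surrogate <- function(model, path) {
  jsonlite::write_json(surrogate_payload(model), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

surrogate_payload <- function(model) {
  if (inherits(model, "mguq_pce")) {
    list(class = "mguq_pce",
         coefficients = as.numeric(model$coefficients),
         index_set = as.integer(model$index_set),
         n_terms = nrow(model$index_set),
         degree = model$degree, q = model$q,
         lower = model$lower, upper = model$upper,
         eps_loo = model$eps_loo, n_train = model$n_train,
         ridge = model$ridge, var_y = model$var_y)
  } else if (inherits(model, "mguq_kriging")) {
    tr <- if (model$trend$type == "constant") list(type = "constant")
          else list(type = "pce", pce = surrogate_payload(model$trend$pce))
    list(class = "mguq_kriging",
         U = as.numeric(model$U), n_train = nrow(model$U),
         Y = model$Y, theta = model$theta, nugget = model$nugget,
         lower = model$lower, upper = model$upper, trend = tr)
  } else if (inherits(model, "mguq_pck")) {
    list(class = "mguq_pck",
         pce_trend = surrogate_payload(model$pce_trend),
         kriging = surrogate_payload(model$kriging))
  } else stop("unsupported surrogate", call. = FALSE)
}

#' Reload a surrogate written by [write_surrogate()]
#'
#' @param path JSON path.
#' @return The reconstructed surrogate object.
#' @export
read_surrogate <- function(path) {
  surrogate_from_payload(jsonlite::read_json(path, simplifyVector = TRUE))
}

surrogate_from_payload <- function(p) {
  if (p$class == "mguq_pce") {
    structure(list(coefficients = p$coefficients,
                   index_set = matrix(as.integer(p$index_set), p$n_terms),
                   degree = p$degree, q = p$q, lower = p$lower,
                   upper = p$upper, eps_loo = p$eps_loo,
                   n_train = p$n_train, ridge = p$ridge, var_y = p$var_y),
              class = "mguq_pce")
  } else if (p$class == "mguq_kriging") {
    U <- matrix(p$U, p$n_train)
    trend <- if (p$trend$type == "constant") list(type = "constant")
             else list(type = "pce", pce = surrogate_from_payload(p$trend$pce))
    Fm <- trend_matrix(trend, U, p$lower, p$upper)
    pr <- krig_profile(U, p$Y, Fm, p$theta, p$nugget)
    obj <- structure(list(U = U, Y = p$Y, Fm = Fm, theta = p$theta,
                          nugget = p$nugget, beta = pr$beta,
                          sigma2 = pr$sigma2, L = pr$L, alpha = pr$alpha,
                          trend = trend, lower = p$lower, upper = p$upper,
                          n_train = length(p$Y), kernel = "matern52"),
                     class = "mguq_kriging")
    obj$eps_loo <- kriging_loo_eps(obj)
    obj
  } else if (p$class == "mguq_pck") {
    krig <- surrogate_from_payload(p$kriging)
    structure(list(pce_trend = surrogate_from_payload(p$pce_trend),
                   kriging = krig, eps_loo = krig$eps_loo,
                   n_train = krig$n_train),
              class = "mguq_pck")
  } else stop("unknown surrogate class in payload", call. = FALSE)
}
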