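#' Model specification: route combination, death mechanism, routes
#'
#' A model spec fixes the structural choices of the buffered multi-route
#' GUTS model: how routes are combined (concentration addition `"CA"`,
#' one shared dominant rate constant acting on the weighted buffer sum;
#' or damage addition `"DA"`, route-specific rate constants with a
#' weighted sum of damages), which death mechanism is used (stochastic
#' death `"SD"` or individual tolerance `"IT"`), the number of uptake
#' routes, and the buffer speed constant `eta`.
#'
#' `eta` (per day) governs the first-order transfer from the external
#' exposure to the buffer state (residues on the exoskeleton or in the
#' gut): `dB/dt = eta * (C(t) - B)`.  It is a fixed structural constant,
#' never calibrated; the default 2/d is a documented placeholder on the
#' time scale of one half-day.
#'
#' For a single route (`n_routes = 1`) CA and DA are mathematically
#' identical and both collapse to the plain buffered GUTS model.
#'
#' @param combination `"CA"` or `"DA"`.
#' @param death `"SD"` or `"IT"`.
#' @param n_routes positive integer number of uptake routes
#'   (route 1 = contact by convention).
#' @param eta buffer speed constant, per day; must be positive.
#' @param route_units character vector of exposure unit labels, one per
#'   route.
#' @return An object of class `bg_spec`.
#' @examples
#' model_spec("CA", "SD", n_routes = 2)
#' @export
model_spec <- function(combination = c("CA", "DA"), death = c("SD", "IT"),
                       n_routes = 1L, eta = 2,
                       route_units = NULL) {
  combination <- match.arg(combination)
  death <- match.arg(death)
  n_routes <- as.integer(n_routes)
  if (n_routes < 1L) stop("n_routes must be >= 1")
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0)
    stop("eta must be a single positive number")
  if (is.null(route_units)) {
    route_units <- if (n_routes == 2L) {
      c("ug a.i./bee", "mg a.i./kg food")
    } else {
      paste0("route", seq_len(n_routes), " unit")
    }
  }
  if (length(route_units) != n_routes)
    stop("route_units must have one entry per route")
  structure(list(combination = combination, death = death,
                 n_routes = n_routes, eta = eta,
                 route_units = route_units),
            class = "bg_spec")
}

#' @export
print.bg_spec <- function(x, ...) {
  cat(sprintf("<bg_spec> BufferGUTS-%s-%s, %d route(s), eta = %g/d\n",
              x$combination, x$death, x$n_routes, x$eta))
  cat("  units:", paste(x$route_units, collapse = ", "), "\n")
  invisible(x)
}

#' Parameter set for a buffered multi-route GUTS model
#'
#' Free parameters of a model variant.  All state variables and threshold
#' parameters are expressed in the exposure unit of route 1; the weights
#' `w[i > 1]` convert route-i exposure into route-1 units (`w[1] = 1` is
#' fixed for identifiability).
#'
#' @param spec a [model_spec()].
#' @param kd dominant rate constant(s), per day: one scalar for CA, one
#'   per route for DA.
#' @param w route weights, length `n_routes` with `w[1] = 1`; a scalar 1
#'   is recycled for a single route.
#' @param z effect threshold in route-1 units (SD only).
#' @param kk killing rate, per route-1 unit per day (SD only).
#' @param alpha median of the individual threshold distribution in
#'   route-1 units (IT only).
#' @param beta shape of the log-logistic threshold distribution,
#'   dimensionless (IT only).
#' @param hb background hazard rate, per day; `hb >= 0`.
#' @return An object of class `bg_params`.
#' @examples
#' sp <- model_spec("CA", "SD", n_routes = 2)
#' param_set(sp, kd = 0.7, w = c(1, 0.05), z = 0.08, kk = 3, hb = 0.02)
#' @export
param_set <- function(spec, kd, w = NULL, z = NULL, kk = NULL,
                      alpha = NULL, beta = NULL, hb = 0) {
  stopifnot(inherits(spec, "bg_spec"))
  N <- spec$n_routes
  if (is.null(w)) w <- rep(1, N)
  if (length(w) != N) stop("w must have one weight per route")
  if (abs(w[1L] - 1) > 0) stop("w[1] must be exactly 1 (route-1 anchoring)")
  if (any(w <= 0)) stop("weights must be positive")
  nk <- if (spec$combination == "CA") 1L else N
  if (length(kd) != nk)
    stop(sprintf("%s with %d route(s) needs %d dominant rate constant(s)",
                 spec$combination, N, nk))
  if (any(kd <= 0)) stop("kd must be positive")
  if (!is.numeric(hb) || hb < 0) stop("hb must be >= 0")
  if (spec$death == "SD") {
    if (is.null(z) || is.null(kk)) stop("SD models need z and kk")
    if (z <= 0 || kk <= 0) stop("z and kk must be positive")
    alpha <- beta <- NA_real_
  } else {
    if (is.null(alpha) || is.null(beta)) stop("IT models need alpha and beta")
    if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
    z <- kk <- NA_real_
  }
  structure(list(kd = as.numeric(kd), w = as.numeric(w),
                 z = as.numeric(z), kk = as.numeric(kk),
                 alpha = as.numeric(alpha), beta = as.numeric(beta),
                 hb = as.numeric(hb)),
            class = "bg_params")
}

#' @export
print.bg_params <- function(x, ...) {
  v <- unlist(x[!vapply(x, function(e) all(is.na(e)), logical(1L))])
  cat("<bg_params>\n")
  print(v)
  invisible(x)
}

#' Names of the free parameters of a model variant
#'
#' Order: rate constants (`kd` or `kd_1 ... kd_N`), weights
#' (`w_2 ... w_N`), death-mechanism parameters (`z`, `kk` or `alpha`,
#' `beta`), then `hb` if included.
#'
#' @inheritParams param_set
#' @param include_hb include the background hazard?
#' @return character vector of parameter names.
#' @export
free_param_names <- function(spec, include_hb = TRUE) {
  N <- spec$n_routes
  kd <- if (spec$combination == "CA") "kd" else paste0("kd_", seq_len(N))
  w <- if (N > 1L) paste0("w_", 2:N) else character()
  death <- if (spec$death == "SD") c("z", "kk") else c("alpha", "beta")
  c(kd, w, death, if (include_hb) "hb")
}

#' Number of free parameters of a model variant
#'
#' CA variants share one dominant rate constant and add one weight per
#' route beyond the first: `N + 2` free parameters.  DA variants carry a
#' rate constant per route: `2N + 1`.  With one route both collapse to 3.
#' The background hazard `hb` adds one more when included.
#'
#' @param combination `"CA"` or `"DA"`.
#' @param death `"SD"` or `"IT"` (both death mechanisms use two
#'   parameters, so the count does not depend on this argument; it is
#'   accepted for a uniform interface).
#' @param n_routes number of uptake routes, `N >= 1`.
#' @param include_hb count the background hazard as a free parameter?
#' @return integer parameter count.
#' @examples
#' n_free_parameters("CA", "SD", 2)        # 4
#' n_free_parameters("DA", "IT", 2)        # 5
#' n_free_parameters("CA", "SD", 1, TRUE)  # 4 = 3 + hb
#' @export
n_free_parameters <- function(combination = c("CA", "DA"),
                              death = c("SD", "IT"),
                              n_routes = 1L, include_hb = FALSE) {
  combination <- match.arg(combination)
  match.arg(death)
  N <- as.integer(n_routes)
  if (N < 1L) stop("n_routes must be >= 1")
  k <- if (combination == "CA") N + 2L else 2L * N + 1L
  k + as.integer(include_hb)
}

# params <-> named vector in free_param_names() order
params_to_vector <- function(spec, params) {
  nm <- free_param_names(spec, include_hb = TRUE)
  N <- spec$n_routes
  v <- c(params$kd,
         if (N > 1L) params$w[-1L],
         if (spec$death == "SD") c(params$z, params$kk)
         else c(params$alpha, params$beta),
         params$hb)
  setNames(v, nm)
}

vector_to_params <- function(spec, v) {
  N <- spec$n_routes
  nk <- if (spec$combination == "CA") 1L else N
  kd <- v[seq_len(nk)]
  w <- c(1, if (N > 1L) v[nk + seq_len(N - 1L)])
  d1 <- v[nk + N - 1L + 1L]
  d2 <- v[nk + N - 1L + 2L]
  hb <- v[nk + N - 1L + 3L]
  if (spec$death == "SD")
    param_set(spec, kd = kd, w = w, z = d1, kk = d2, hb = hb)
  else
    param_set(spec, kd = kd, w = w, alpha = d1, beta = d2, hb = hb)
}
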