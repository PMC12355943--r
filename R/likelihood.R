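#' Survival dataset: observed counts with route-tagged exposures
#'
#' A survival dataset bundles, per treatment, the exposure profiles for
#' every uptake route and the observed survivor counts over time.
#' Treatments from several tests (acute contact, acute oral, chronic
#' oral) of the same substance are calibrated jointly.
#'
#' @param treatments list; each element is a list with fields
#'   `profiles` (list of [exposure_profile()], one per route, in route
#'   order — routes without exposure in a design get an empty profile),
#'   `times` (observation times, days, starting at 0), `n_alive`
#'   (survivor counts, non-increasing, `n_alive[1]` = individuals at
#'   start) and optionally `id` / `test_id` labels.
#' @param n_routes number of uptake routes every treatment must cover.
#' @return an object of class `bg_dataset`.
#' @export
survival_dataset <- function(treatments, n_routes = NULL) {
  stopifnot(length(treatments) >= 1L)
  if (is.null(n_routes))
    n_routes <- length(treatments[[1L]]$profiles)
  for (k in seq_along(treatments)) {
    tr <- treatments[[k]]
    if (length(tr$profiles) != n_routes)
      stop("treatment ", k, ": expected ", n_routes, " route profile(s)")
    if (length(tr$times) != length(tr$n_alive))
      stop("treatment ", k, ": times and n_alive differ in length")
    if (is.unsorted(tr$times) || tr$times[1L] != 0)
      stop("treatment ", k, ": observation times must be sorted from 0")
    if (any(diff(tr$n_alive) > 0))
      stop("treatment ", k, ": survivor counts increase over time")
    if (is.null(tr$id)) treatments[[k]]$id <- paste0("treatment_", k)
  }
  structure(list(treatments = treatments, n_routes = as.integer(n_routes)),
            class = "bg_dataset")
}

#' @export
print.bg_dataset <- function(x, ...) {
  n0 <- vapply(x$treatments, function(tr) tr$n_alive[1L], numeric(1L))
  cat(sprintf("<bg_dataset> %d treatment(s), %d route(s), %d individuals\n",
              length(x$treatments), x$n_routes, sum(n0)))
  invisible(x)
}

# Precompute per-treatment forcing + observations for the C++ likelihood.
pack_dataset <- function(dataset, spec) {
  stopifnot(inherits(dataset, "bg_dataset"))
  if (dataset$n_routes != spec$n_routes)
    stop("dataset has ", dataset$n_routes, " route(s) but spec expects ",
         spec$n_routes)
  lapply(dataset$treatments, function(tr) {
    f <- build_forcing(tr$profiles, t_max = max(tr$times, 1e-9))
    list(breakpoints = f$breakpoints, levels = f$levels,
         obs_t = as.numeric(tr$times), n_alive = as.integer(tr$n_alive))
  })
}

#' Multinomial survival log-likelihood
#'
#' The GUTS survival likelihood: deaths are multinomially distributed
#' over the observation intervals.  For a treatment observed at times
#' `t_0 = 0 < t_1 < ... < t_J` with survivor counts `n_j`, the
#' `d_j = n_(j-1) - n_j` deaths in interval `j` contribute
#' `d_j * log(S(t_(j-1)) - S(t_j))` and the final survivors contribute
#' `n_J * log S(t_J)`; contributions are summed over treatments.  The
#' parameter-independent multinomial coefficient is dropped.  Interval
#' probabilities are floored at `1e-12` before taking logs so that an
#' observed death in an interval where the model predicts none yields a
#' large finite penalty instead of `-Inf`.
#'
#' @param spec a [model_spec()].
#' @param params a [param_set()].
#' @param dataset a [survival_dataset()], or the result of an internal
#'   pre-packing for repeated evaluation.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(spec, params, dataset) {
  packed <- if (inherits(dataset, "bg_dataset")) pack_dataset(dataset, spec)
            else dataset
  loglik_packed(spec, params, packed)
}

loglik_packed <- function(spec, params, packed) {
  bg_loglik_cpp(
    packed,
    combination = match(spec$combination, c("CA", "DA")) - 1L,
    death = match(spec$death, c("SD", "IT")) - 1L,
    eta = spec$eta, kd = params$kd, w = params$w,
    z = if (is.na(params$z)) 1 else params$z,
    kk = if (is.na(params$kk)) 0 else params$kk,
    alpha = if (is.na(params$alpha)) 1 else params$alpha,
    beta = if (is.na(params$beta)) 1 else params$beta,
    hb = params$hb)
}

#' Predicted survivor counts at the observation times
#'
#' Expected survivors `n_start * S(t_j)` for every treatment, aligned
#' with the observed counts; the shared input of the NRMSE fit metric.
#'
#' @inheritParams log_likelihood
#' @return data frame with `treatment`, `time_d`, `observed`,
#'   `predicted`.
#' @export
predicted_counts <- function(spec, params, dataset) {
  stopifnot(inherits(dataset, "bg_dataset"))
  out <- lapply(dataset$treatments, function(tr) {
    sim <- simulate_bufferguts(spec, params, tr$profiles,
                               times = unique(c(0, tr$times)))
    S <- sim$S[match(tr$times, sim$time_d)]
    data.frame(treatment = tr$id, time_d = tr$times,
               observed = tr$n_alive, predicted = tr$n_alive[1L] * S)
  })
  do.call(rbind, out)
}
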