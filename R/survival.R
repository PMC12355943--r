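#' Death mechanisms applied to a damage trace
#'
#' These are the two GUTS death mechanisms as standalone operations on a
#' tabulated damage time course `D(t)` (interpreted as piecewise linear
#' between the supplied times).  Inside [simulate_bufferguts()] the same
#' mechanisms are evaluated on the exact exponential representation of
#' `D`; these trace-based versions are the building blocks for working
#' with externally supplied damage curves and for cross-checks.
#'
#' Stochastic death (SD): every individual shares a deterministic hazard
#' proportional to the exceedance of the damage over the threshold,
#' `h(t) = kk * max(0, D(t) - z) + hb`, so
#' `S(t) = exp(-integral_0^t h)`.  The exceedance integral is evaluated
#' exactly on the piecewise-linear representation, including partial
#' segments where `D` crosses `z`.
#'
#' Individual tolerance (IT): each individual draws a fixed threshold
#' from a log-logistic distribution with median `alpha` and shape
#' `beta`; it dies when the running maximum of the damage first exceeds
#' its threshold, so
#' `S(t) = (1 - F(max_{tau <= t} D(tau))) * exp(-hb t)` with
#' `F(x) = 1 / (1 + (x / alpha)^(-beta))`.
#'
#' @param times sorted time grid, days, starting at 0.
#' @param D damage values at `times` (route-1 exposure units), `D >= 0`.
#' @param z effect threshold, route-1 units, `z > 0`.
#' @param kk killing rate, per route-1 unit per day, `kk > 0`.
#' @param alpha median individual threshold, route-1 units, `alpha > 0`.
#' @param beta log-logistic shape, `beta > 0`.
#' @param hb background hazard, per day, `hb >= 0`.
#' @return numeric vector `S(times)`.
#' @examples
#' tt <- seq(0, 10, by = 0.5)
#' D <- pmax(0, 2 - 0.3 * tt)       # decaying damage
#' survival_sd(tt, D, z = 1, kk = 0.1, hb = 0)
#' survival_it(tt, D, alpha = 2.5, beta = 3, hb = 0.01)
#' @export
survival_sd <- function(times, D, z, kk, hb = 0) {
  check_trace(times, D)
  if (z <= 0 || kk <= 0 || hb < 0)
    stop("need z > 0, kk > 0, hb >= 0")
  n <- length(times)
  exc <- numeric(n)
  for (j in seq_len(n - 1L)) {
    exc[j + 1L] <- exc[j] +
      linseg_exceedance(times[j], times[j + 1L], D[j], D[j + 1L], z)
  }
  exp(-(kk * exc + hb * times))
}

# exact integral of max(0, D - z) over [t0, t1] for linear D
linseg_exceedance <- function(t0, t1, d0, d1, z) {
  dt <- t1 - t0
  if (dt <= 0) return(0)
  a0 <- d0 - z; a1 <- d1 - z
  if (a0 <= 0 && a1 <= 0) return(0)
  if (a0 >= 0 && a1 >= 0) return(dt * (a0 + a1) / 2)
  tc <- dt * a0 / (a0 - a1)  # crossing offset from t0
  if (a0 > 0) tc * a0 / 2 else (dt - tc) * a1 / 2
}

#' @rdname survival_sd
#' @export
survival_it <- function(times, D, alpha, beta, hb = 0) {
  check_trace(times, D)
  if (alpha <= 0 || beta <= 0 || hb < 0)
    stop("need alpha > 0, beta > 0, hb >= 0")
  M <- cummax(D)
  FF <- ifelse(M <= 0, 0, 1 / (1 + (M / alpha)^(-beta)))
  (1 - FF) * exp(-hb * times)
}

check_trace <- function(times, D) {
  if (length(times) != length(D))
    stop("times and D must have equal length")
  if (length(times) < 1L || is.unsorted(times))
    stop("times must be sorted")
  if (any(D < -1e-12)) stop("damage trace must be non-negative")
  invisible(TRUE)
}
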