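# Numeric solver backend: the same state system integrated with
# deSolve::lsoda, segment by segment so the piecewise-constant forcing
# never crosses an integration step discontinuously.  Used as an
# independent cross-check of the analytic backend (tolerances 1e-10 /
# 1e-12).  For the IT running maximum the damage is recorded on a fine
# internal grid and local maxima are sharpened by parabolic
# interpolation, so the backend is grid-converged well below 1e-6.
ode_backend <- function(spec, params, forcing, times, rtol = 1e-10,
                        atol = 1e-12, fine_dt = 1 / 1440) {
  N <- spec$n_routes
  da <- spec$combination == "DA"
  sd_mech <- spec$death == "SD"
  kd <- params$kd
  w <- params$w
  eta <- spec$eta

  deriv <- function(t, y, parms) {
    C <- parms$C
    B <- y[seq_len(N)]
    dB <- eta * (C - B)
    if (da) {
      Dr <- y[N + seq_len(N)]
      dDr <- kd * (B - Dr)
      D <- sum(w * Dr)
      dH <- if (sd_mech) params$kk * max(0, D - params$z) else 0
      list(c(dB, dDr, dH))
    } else {
      D <- y[N + 1L]
      dD <- kd[1L] * (sum(w * B) - D)
      dH <- if (sd_mech) params$kk * max(0, D - params$z) else 0
      list(c(dB, dD, dH))
    }
  }

  nstate <- if (da) 2L * N + 1L else N + 2L
  y <- numeric(nstate)
  bk <- forcing$breakpoints
  out_t <- times
  # union grid: output times + fine grid per segment (for the IT maximum)
  grid_all <- out_t
  if (!sd_mech) {
    for (seg in seq_len(length(bk) - 1L))
      grid_all <- c(grid_all,
                    seq(bk[seg], bk[seg + 1L], by = fine_dt))
  }
  grid_all <- sort(unique(c(grid_all, bk)))
  recs <- matrix(NA_real_, nrow = length(grid_all), ncol = nstate)
  recs[1L, ] <- 0
  for (seg in seq_len(length(bk) - 1L)) {
    t0 <- bk[seg]; t1 <- bk[seg + 1L]
    loc <- grid_all[grid_all > t0 & grid_all <= t1]
    grid <- sort(unique(c(t0, loc)))
    sol <- deSolve::lsoda(y, grid, deriv,
                          parms = list(C = forcing$levels[, seg]),
                          rtol = rtol, atol = atol)
    if (length(loc))
      recs[match(loc, grid_all), ] <- sol[match(loc, grid), -1L,
                                          drop = FALSE]
    y <- as.numeric(sol[nrow(sol), -1L])
  }

  B <- recs[, seq_len(N), drop = FALSE]
  if (da) {
    Droutes <- recs[, N + seq_len(N), drop = FALSE]
    D <- as.vector(Droutes %*% w)
  } else {
    Droutes <- NULL
    D <- recs[, N + 1L]
  }
  Hexc <- recs[, nstate]
  if (sd_mech) {
    H <- Hexc + params$hb * grid_all
    S <- exp(-H)
  } else {
    # sharpen interior local maxima of D by parabolic interpolation
    Dadj <- D
    n <- length(D)
    if (n >= 3L) {
      for (i in 2:(n - 1L)) {
        if (D[i] >= D[i - 1L] && D[i] >= D[i + 1L]) {
          h1 <- grid_all[i] - grid_all[i - 1L]
          h2 <- grid_all[i + 1L] - grid_all[i]
          d1 <- (D[i] - D[i - 1L]) / h1
          d2 <- (D[i + 1L] - D[i]) / h2
          curv <- (d2 - d1) / ((h1 + h2) / 2)
          if (curv < 0) Dadj[i] <- D[i] - (d1 + (d2 - d1) *
            h1 / (h1 + h2))^2 / (2 * curv)
        }
      }
    }
    M <- cummax(Dadj)
    FF <- ifelse(M <= 0, 0, 1 / (1 + (M / params$alpha)^(-params$beta)))
    S <- (1 - FF) * exp(-params$hb * grid_all)
    H <- params$hb * grid_all
  }
  sel <- match(out_t, grid_all)
  out <- list(S = S[sel], D = D[sel], H = H[sel],
              B = B[sel, , drop = FALSE])
  if (da) out$D_routes <- Droutes[sel, , drop = FALSE]
  out
}
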