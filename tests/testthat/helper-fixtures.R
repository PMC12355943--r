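# Shared fixtures: small specs, parameter sets and a random-instance
# generator used by the unit and property tests.

spec1 <- function(death = "SD", eta = 2) {
  model_spec("CA", death, n_routes = 1, eta = eta,
             route_units = "ug a.i./bee")
}

spec2 <- function(combination = "CA", death = "SD", eta = 2) {
  model_spec(combination, death, n_routes = 2, eta = eta)
}

params_for <- function(spec, kd = 0.7, w2 = 0.05, hb = 0) {
  kd <- rep(kd, length.out = if (spec$combination == "CA") 1L
            else spec$n_routes)
  w <- c(1, rep(w2, spec$n_routes - 1L))
  if (spec$death == "SD")
    param_set(spec, kd = kd, w = w, z = 0.08, kk = 3, hb = hb)
  else
    param_set(spec, kd = kd, w = w, alpha = 0.2, beta = 2, hb = hb)
}

empty_profile <- function(route, unit = "u") {
  exposure_profile(route, unit, numeric(), numeric(), numeric())
}

pulse1h <- function(level, route = 1L, unit = "ug a.i./bee") {
  exposure_profile(route, unit, 0, 1 / 24, level)
}

# random model instance (spec, params, profiles) for property tests
random_instance <- function(max_routes = 2L, t_end = 8) {
  N <- sample(seq_len(max_routes), 1L)
  comb <- sample(c("CA", "DA"), 1L)
  death <- sample(c("SD", "IT"), 1L)
  sp <- model_spec(comb, death, N, eta = runif(1, 0.5, 5))
  kd <- runif(if (comb == "CA") 1L else N, 0.1, 3)
  w <- c(1, if (N > 1L) runif(N - 1L, 0.01, 2))
  args <- list(sp, kd = kd, w = w, hb = runif(1, 0, 0.05))
  if (death == "SD") {
    args$z <- runif(1, 0.01, 0.5); args$kk <- runif(1, 0.1, 5)
  } else {
    args$alpha <- runif(1, 0.05, 1); args$beta <- runif(1, 0.5, 5)
  }
  profiles <- lapply(seq_len(N), function(r) {
    ns <- sample(1:3, 1L)
    st <- sort(sample(0:(8 * t_end - 2), ns)) / 8
    en <- pmin(st + sample(1:4, ns, replace = TRUE) / 8,
               c(st[-1L], t_end))
    ok <- en > st
    exposure_profile(r, sp$route_units[r], st[ok], en[ok],
                     runif(sum(ok), 0, 2))
  })
  list(spec = sp, params = do.call(param_set, args), profiles = profiles)
}

# ground truth + templates of the standard synthetic recovery study
recovery_truth <- function() {
  sp <- spec2("CA", "SD")
  list(spec = sp,
       params = param_set(sp, kd = 0.7, w = c(1, 0.05), z = 0.08,
                          kk = 3, hb = 0.02))
}
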