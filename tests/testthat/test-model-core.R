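tt_daily <- seq(0, 8, by = 1 / 4)

test_that("no exposure and no background hazard give S identically 1", {
  sp <- spec1()
  tr <- simulate_bufferguts(sp, params_for(sp), list(empty_profile(1)),
                            tt_daily)
  expect_equal(tr$S, rep(1, length(tt_daily)))
  expect_equal(tr$D, rep(0, length(tt_daily)))
})

test_that("large eta reproduces the reduced-GUTS damage closed form", {
  # with a fast buffer (eta = 1e4/d) and constant exposure c the damage
  # approaches the classic c * (1 - exp(-kd t))
  sp <- model_spec("CA", "SD", 1, eta = 1e4, route_units = "u")
  pr <- params_for(sp, kd = 0.5)
  cst <- exposure_profile(1, "u", 0, 10, 2)
  tt <- seq(0, 10, by = 0.25)
  tr <- simulate_bufferguts(sp, pr, list(cst), tt)
  Dred <- 2 * (1 - exp(-0.5 * tt))
  expect_lt(max(abs(tr$D - Dred) / pmax(Dred, 1e-6)), 1e-3)
})

test_that("CA and DA are identical for a single route", {
  set.seed(101)
  for (death in c("SD", "IT")) {
    spCA <- model_spec("CA", death, 1, eta = 1.7, route_units = "u")
    spDA <- model_spec("DA", death, 1, eta = 1.7, route_units = "u")
    pr <- params_for(spCA)
    prof <- list(exposure_profile(1, "u", c(0, 2), c(1 / 24, 2.5),
                                  c(0.9, 0.4)))
    a <- simulate_bufferguts(spCA, pr, prof, tt_daily)
    b <- simulate_bufferguts(spDA, params_for(spDA), prof, tt_daily)
    expect_lt(max(abs(a$D - b$D)), 1e-10)
    expect_lt(max(abs(a$S - b$S)), 1e-10)
  }
})

test_that("DA with shared kinetics equals CA for any weights", {
  # when all routes share one dominant rate constant it does not matter
  # whether exposures or damages are summed: the cascade is linear
  set.seed(7)
  for (i in 1:10) {
    k <- runif(1, 0.2, 2); w2 <- runif(1, 0.01, 2)
    spCA <- spec2("CA"); spDA <- spec2("DA")
    pCA <- param_set(spCA, kd = k, w = c(1, w2), z = 0.08, kk = 3,
                     hb = 0.01)
    pDA <- param_set(spDA, kd = c(k, k), w = c(1, w2), z = 0.08, kk = 3,
                     hb = 0.01)
    profs <- list(pulse1h(runif(1, 0.1, 2)),
                  exposure_profile(2, "mg a.i./kg food", 0, 0.25,
                                   runif(1, 5, 40)))
    a <- simulate_bufferguts(spCA, pCA, profs, tt_daily)
    b <- simulate_bufferguts(spDA, pDA, profs, tt_daily)
    expect_lt(max(abs(a$D - b$D)), 1e-8)
    expect_lt(max(abs(a$S - b$S)), 1e-8)
  }
})

test_that("route-1 anchoring: scaling route-2 exposure against its weight", {
  # multiplying the route-2 exposure by c and dividing w_2 by c leaves
  # the combined damage and survival unchanged
  for (comb in c("CA", "DA")) {
    sp <- spec2(comb)
    kd <- if (comb == "CA") 0.6 else c(0.6, 1.4)
    base <- param_set(sp, kd = kd, w = c(1, 0.05), z = 0.08, kk = 3,
                      hb = 0.01)
    scaled <- param_set(sp, kd = kd, w = c(1, 0.05 / 7), z = 0.08, kk = 3,
                        hb = 0.01)
    oral <- exposure_profile(2, "mg a.i./kg food", 0, 0.25, 20)
    oral7 <- exposure_profile(2, "mg a.i./kg food", 0, 0.25, 20 * 7)
    a <- simulate_bufferguts(sp, base, list(pulse1h(0.3), oral), tt_daily)
    b <- simulate_bufferguts(sp, scaled, list(pulse1h(0.3), oral7),
                             tt_daily)
    expect_equal(a$D, b$D, tolerance = 1e-12)
    expect_equal(a$S, b$S, tolerance = 1e-12)
  }
})

test_that("analytic and numeric backends agree on random instances", {
  set.seed(202)
  for (i in 1:25) {
    inst <- random_instance()
    tt <- seq(0, 8, by = 1 / 24)
    a <- simulate_bufferguts(inst$spec, inst$params, inst$profiles, tt)
    b <- simulate_bufferguts(inst$spec, inst$params, inst$profiles, tt,
                             backend = "ode")
    expect_lt(max(abs(a$S - b$S)), 1e-6)
    expect_lt(max(abs(a$D - b$D) / pmax(abs(b$D), 1e-6)), 1e-6)
  }
})

test_that("survival is non-increasing on random trajectories", {
  set.seed(303)
  for (i in 1:40) {
    inst <- random_instance()
    tr <- simulate_bufferguts(inst$spec, inst$params, inst$profiles,
                              seq(0, 8, by = 1 / 12))
    expect_true(all(diff(tr$S) <= 1e-12))
    expect_true(all(tr$S >= 0 & tr$S <= 1))
    expect_true(all(tr$D >= -1e-12))
    expect_equal(tr$S[1L], 1)
  }
})

test_that("simulate validates its inputs", {
  sp <- spec2()
  pr <- params_for(sp)
  expect_error(simulate_bufferguts(sp, pr, list(pulse1h(1)), 0:2),
               "expected 2 exposure profile")
  expect_error(simulate_bufferguts(sp, pr,
                                   list(pulse1h(1), empty_profile(2)),
                                   c(0, 2, 1)),
               "increasing")
})
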