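test_that("acute-oral dose converts to food concentration at 20 mg/bee", {
  # worked examples from the bundled regulatory-test summary
  expect_equal(convert_acute_oral_dose(0.0336), 1.68)
  expect_equal(convert_acute_oral_dose(0.136), 6.80)
  expect_equal(signif(convert_acute_oral_dose(0.0327), 3), 1.64)
  expect_equal(convert_acute_oral_dose(0.00348), 0.174)
  expect_equal(convert_acute_oral_dose(0), 0)
  expect_error(convert_acute_oral_dose(1, 0), "positive")
})

test_that("the conversion is linear and invertible", {
  x <- c(0.01, 0.5, 17.5)
  expect_equal(convert_food_conc_to_dose(convert_acute_oral_dose(x)), x)
  expect_equal(convert_acute_oral_dose(2 * x),
               2 * convert_acute_oral_dose(x))
})

test_that("designs discretise onto the 1-hour grid", {
  ac <- discretize_design("acute_contact", 0.262)
  expect_equal(ac$segments, data.frame(t_start = 0, t_end = 1 / 24,
                                       level = 0.262))
  expect_equal(ac$route_id, 1L)
  # the 1-h pulse preserves the nominal dose-hour area under the curve
  expect_equal(with(ac$segments, (t_end - t_start) * level) * 24, 0.262)

  ao <- discretize_design("acute_oral", 0.0336, feeding_duration_h = 6)
  expect_equal(ao$segments$t_end, 0.25)
  expect_equal(ao$segments$level, 1.68)
  expect_equal(ao$route_id, 2L)
  # sub-hour feeding snaps up to a full hour
  expect_equal(discretize_design("acute_oral", 1,
                                 feeding_duration_h = 0.4)$segments$t_end,
               1 / 24)
  expect_error(discretize_design("acute_oral", 1, feeding_duration_h = 7),
               "6")

  co <- discretize_design("chronic_oral", 18.0, test_duration_d = 10)
  expect_equal(co$segments, data.frame(t_start = 0, t_end = 10,
                                       level = 18.0))
})

test_that("replicate batches sum elementwise", {
  a <- list(times = 0:2, n_alive = c(10, 8, 7))
  b <- list(times = 0:2, n_alive = c(10, 9, 9))
  expect_equal(sum_replicates(list(a, b))$n_alive, c(20, 17, 16))
  expect_equal(sum_replicates(list(a))$n_alive, a$n_alive)
  expect_error(sum_replicates(list(a, list(times = c(0, 1, 3),
                                           n_alive = c(10, 9, 9)))),
               "same observation times")
})

test_that("summing replicates shifts the log-likelihood by a constant", {
  # conditional-binomial likelihood of the pooled record equals the sum
  # of per-replicate likelihoods up to a parameter-independent constant
  sp <- spec1()
  prof <- list(exposure_profile(1, "ug a.i./bee", 0, 2, 1.2))
  reps <- list(c(10, 8, 5), c(10, 9, 6))
  mk <- function(n_alive) list(profiles = prof, times = 0:2,
                               n_alive = n_alive)
  ds_sep <- survival_dataset(lapply(reps, mk), n_routes = 1)
  pooled <- sum_replicates(lapply(reps, function(r)
    list(times = 0:2, n_alive = r)))
  ds_sum <- survival_dataset(list(mk(pooled$n_alive)), n_routes = 1)
  deltas <- vapply(seq(0.2, 1.4, by = 0.3), function(kd) {
    pr <- params_for(sp, kd = kd, hb = 0.01)
    log_likelihood(sp, pr, ds_sum) - log_likelihood(sp, pr, ds_sep)
  }, numeric(1))
  expect_lt(diff(range(deltas)), 1e-9)
})

test_that("pooling does not move the 1-parameter likelihood optimum", {
  sp <- spec1()
  prof <- list(exposure_profile(1, "ug a.i./bee", 0, 2, 1.2))
  reps <- list(c(10, 8, 5), c(10, 9, 6))
  mk <- function(n_alive) list(profiles = prof, times = 0:2,
                               n_alive = n_alive)
  ds_sep <- survival_dataset(lapply(reps, mk), n_routes = 1)
  pooled <- sum_replicates(lapply(reps, function(r)
    list(times = 0:2, n_alive = r)))
  ds_sum <- survival_dataset(list(mk(pooled$n_alive)), n_routes = 1)
  kk_grid <- seq(0.5, 8, by = 0.05)
  ll <- function(ds) vapply(kk_grid, function(kk) {
    pr <- param_set(sp, kd = 0.7, z = 0.08, kk = kk, hb = 0.01)
    log_likelihood(sp, pr, ds)
  }, numeric(1))
  expect_equal(kk_grid[which.max(ll(ds_sum))],
               kk_grid[which.max(ll(ds_sep))])
})

test_that("the outlier filter flags the three discordant acute-oral tests", {
  tab <- load_regulatory_tests()
  expect_equal(nrow(tab), 29L)
  res <- exclude_outlier_tests(tab)
  flagged <- res[res$excluded, c("compound", "report_no")]
  expect_equal(sum(res$excluded), 3L)
  expect_equal(sum(!res$excluded), 26L)
  expect_setequal(paste(flagged$compound, flagged$report_no),
                  c("Deltamethrin M-444971", "Imidacloprid M-006940",
                    "Tetraniliprole M-441758"))
})

test_that("concordant acute-oral tests are never flagged", {
  tab <- data.frame(
    compound = "X", report_no = c("r1", "r2", "r3"),
    design = c("acute_oral", "acute_oral", "chronic_oral"),
    ld50_48h_ug_bee = c(0.10, 0.15, NA),
    lc50_chronic_mg_kg = c(NA, NA, 3))
  expect_false(any(exclude_outlier_tests(tab)$excluded))
})
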