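test_that("generation is deterministic in the seed", {
  rt <- recovery_truth()
  tmpl <- design_template("acute_contact", levels = c(2, 10),
                          n_per_treatment = 20)
  a <- generate_dataset(rt$spec, rt$params, tmpl, seed = 11)
  b <- generate_dataset(rt$spec, rt$params, tmpl, seed = 11)
  c <- generate_dataset(rt$spec, rt$params, tmpl, seed = 12)
  get_counts <- function(ds) lapply(ds$treatments, `[[`, "n_alive")
  expect_identical(get_counts(a), get_counts(b))
  expect_false(identical(get_counts(a), get_counts(c)))
})

test_that("without hazard or exposure nobody dies", {
  sp <- spec2()
  pr <- param_set(sp, kd = 0.7, w = c(1, 0.05), z = 0.08, kk = 3, hb = 0)
  tmpl <- design_template("chronic_oral", levels = 0,
                          n_per_treatment = 50)
  ds <- generate_dataset(sp, pr, tmpl, seed = 1)
  expect_equal(ds$treatments[[1]]$n_alive, rep(50L, 11))
})

test_that("generated counts are non-increasing", {
  rt <- recovery_truth()
  tmpl <- default_study_templates(rt$spec, rt$params,
                                  n_per_treatment = 10)
  ds <- generate_dataset(rt$spec, rt$params, tmpl, seed = 3)
  for (tr in ds$treatments) expect_true(all(diff(tr$n_alive) <= 0))
})

test_that("empirical survival converges to the model curve", {
  # law of large numbers: at n = 1e5 individuals the empirical fraction
  # stays within 3 binomial standard errors of S(t) at every time
  rt <- recovery_truth()
  tmpl <- design_template("chronic_oral", levels = 8,
                          n_per_treatment = 1e5)
  ds <- generate_dataset(rt$spec, rt$params, tmpl, seed = 21)
  tr <- ds$treatments[[which(vapply(ds$treatments, `[[`, numeric(1),
                                    "level") > 0)]]
  sim <- simulate_bufferguts(rt$spec, rt$params, tr$profiles, tr$times)
  frac <- tr$n_alive / tr$n_alive[1]
  se <- sqrt(pmax(sim$S * (1 - sim$S), 1e-12) / tr$n_alive[1])
  expect_true(all(abs(frac - sim$S) <= 3 * se + 1e-9))
})

test_that("the level50 finder hits 50% end survival", {
  rt <- recovery_truth()
  tmpl <- design_template("acute_oral", levels = 1, n_per_treatment = 10)
  l50 <- find_level50(rt$spec, rt$params, tmpl)
  pr <- bufferguts:::template_profiles(tmpl, l50, 2)
  sim <- simulate_bufferguts(rt$spec, rt$params, pr, times = c(0, 2))
  expect_equal(sim$S[2], 0.5, tolerance = 1e-4)
})

test_that("the validation suite spans 1- and 2-day oral windows", {
  sc <- make_validation_suite(contact_dose = 0.12, oral_level = 20)
  expect_setequal(unique(sc$oral_duration[sc$scenario != "control" &
                                          sc$oral_level > 0]), c(1, 2))
  # a zero-delay scenario overlaps the contact pulse and the oral window
  expect_true(any(sc$oral_start == 0 & sc$oral_level > 0))
  expect_true("control" %in% sc$scenario)
})

test_that("all scenarios share the control's background survival", {
  rt <- recovery_truth()
  pr <- rt$params
  sc <- make_validation_suite(contact_dose = 0.12, oral_level = 20,
                              delays = c(0, 2), horizon = 6)
  out <- simulate_validation_suite(rt$spec, pr, sc, dt = 0.5)
  ctrl <- out[out$scenario == "control", ]
  expect_equal(ctrl$S, exp(-pr$hb * ctrl$time_d), tolerance = 1e-12)
})

test_that("a synthetic study round-trips through the CSV interface", {
  rt <- recovery_truth()
  tmpl <- list(design_template("acute_contact", levels = c(5, 20),
                               n_per_treatment = 10),
               design_template("chronic_oral", levels = c(2, 8),
                               n_per_treatment = 10))
  dir <- withr::local_tempdir()
  ds <- write_synthetic_study(rt$spec, rt$params, tmpl, seed = 4,
                              dir = dir)
  expect_true(all(file.exists(file.path(dir, c("exposures.csv",
                                               "survival.csv",
                                               "manifest.json")))))
  back <- read_survival_csv(file.path(dir, "exposures.csv"),
                            file.path(dir, "survival.csv"))
  expect_equal(length(back$treatments), length(ds$treatments))
  counts <- function(d) unname(lapply(d$treatments, `[[`, "n_alive"))
  expect_setequal(unlist(counts(back)), unlist(counts(ds)))
  # likelihoods agree between the in-memory and round-tripped datasets
  expect_equal(log_likelihood(rt$spec, rt$params, back),
               log_likelihood(rt$spec, rt$params, ds))
})
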