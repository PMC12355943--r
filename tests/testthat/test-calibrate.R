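small_study <- function(seed = 5) {
  rt <- recovery_truth()
  tmpl <- list(design_template("acute_contact", levels = c(5, 20, 80),
                               n_per_treatment = 30),
               design_template("chronic_oral", levels = c(1, 4, 16),
                               n_per_treatment = 30))
  generate_dataset(rt$spec, rt$params, tmpl, seed = seed)
}

test_that("the chain filter drops stuck and bad-likelihood chains", {
  # plant one chain stuck at a point (sd = 0) and one on a clearly worse
  # pseudolocal mode; both must go, all healthy chains must stay
  nd <- 50; npar <- 3; nch <- 5
  set.seed(1)
  draws <- array(rlnorm(nd * npar * nch), dim = c(nd, npar, nch),
                 dimnames = list(NULL, c("kd", "z", "kk"), NULL))
  draws[, , 4] <- 1  # stuck
  ll <- matrix(rnorm(nd * nch, mean = -100, sd = 1), nd, nch)
  ll[, 5] <- -250    # more than 100% worse than the best mean
  res <- structure(list(method = "mcmc", draws = draws, loglik = ll,
                        chain_stats = data.frame(
                          chain = 1:nch, mean_loglik = colMeans(ll),
                          min_param_sd = apply(draws, 3, function(m)
                            min(apply(m, 2, sd))),
                          accept_rate = rep(0.3, nch)),
                        kept_chains = rep(TRUE, nch)),
                   class = "bg_calibration")
  out <- filter_chains(res)
  expect_equal(out$kept_chains, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # a chain "only" 50% worse than the best is retained
  ll[, 5] <- -150
  res$loglik <- ll
  res$chain_stats$mean_loglik <- colMeans(ll)
  out2 <- filter_chains(res)
  expect_equal(out2$kept_chains, c(TRUE, TRUE, TRUE, FALSE, TRUE))
})

test_that("identical chains are all kept and quantiles are ordered", {
  nd <- 40
  set.seed(2)
  one <- matrix(rlnorm(nd * 2), nd, 2, dimnames = list(NULL, c("kd", "z")))
  draws <- array(rep(one, 3), dim = c(nd, 2, 3),
                 dimnames = list(NULL, c("kd", "z"), NULL))
  ll <- matrix(-50, nd, 3)
  res <- structure(list(method = "mcmc", draws = draws, loglik = ll,
                        chain_stats = data.frame(
                          chain = 1:3, mean_loglik = colMeans(ll),
                          min_param_sd = apply(draws, 3, function(m)
                            min(apply(m, 2, sd))),
                          accept_rate = rep(0.3, 3)),
                        kept_chains = rep(TRUE, 3)),
                   class = "bg_calibration")
  out <- filter_chains(res)
  expect_true(all(out$kept_chains))
  q <- out$quantiles
  expect_true(all(q$q2.5 <= q$q50 & q$q50 <= q$q97.5))
})

test_that("posterior quantiles are invariant to chain order", {
  nd <- 30
  set.seed(3)
  draws <- array(rlnorm(nd * 2 * 4), dim = c(nd, 2, 4),
                 dimnames = list(NULL, c("kd", "z"), NULL))
  base <- structure(list(method = "mcmc", draws = draws,
                         loglik = matrix(-10, nd, 4),
                         kept_chains = rep(TRUE, 4)),
                    class = "bg_calibration")
  perm <- base
  perm$draws <- draws[, , c(3, 1, 4, 2)]
  expect_equal(posterior_quantiles(base), posterior_quantiles(perm))
})

test_that("MCMC calibration is deterministic given the seed", {
  ds <- small_study()
  rt <- recovery_truth()
  st <- calibration_settings(n_chains = 2, n_warmup = 100, n_draws = 100,
                             seed = 42)
  a <- calibrate(rt$spec, ds, settings = st)
  b <- calibrate(rt$spec, ds, settings = st)
  expect_identical(a$draws, b$draws)
  expect_identical(a$kept_chains, b$kept_chains)
})

test_that("ML mode agrees with the MCMC posterior on an identifiable toy", {
  rt <- recovery_truth()
  tmpl <- default_study_templates(rt$spec, rt$params, n_levels = 5,
                                  n_per_treatment = 60)
  ds <- generate_dataset(rt$spec, rt$params, tmpl, seed = 9)
  ml <- calibrate(rt$spec, ds, settings = calibration_settings(
    n_starts = 6, seed = 3), method = "ml")
  mc <- calibrate(rt$spec, ds, settings = calibration_settings(
    n_chains = 8, n_warmup = 1000, n_draws = 1000, seed = 3))
  q <- mc$quantiles
  est <- ml$mle[q$parameter]
  # the ML optimum falls inside every marginal credible interval
  expect_true(all(est >= q$q2.5 & est <= q$q97.5))
  # and matches the medians within sampling error
  expect_lt(max(abs(log(est / q$q50))), log(1.5))
})
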