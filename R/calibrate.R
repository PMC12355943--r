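#' Default weakly informative priors
#'
#' Log-normal priors for every free parameter of a variant.  These are
#' deliberately broad defaults for calibration to honeybee-scale data
#' (rates of order 0.1-10/d, thresholds in route-1 exposure units of
#' order 0.01-10): rates and thresholds get `lnorm(meanlog = 0,
#' sdlog = 2)` (95% mass roughly 0.02-50), the background hazard
#' `lnorm(log(0.02), 1.5)` (control mortality of a few percent per day),
#' and the log-logistic shape `lnorm(log(2), 1)`.  Replace them with
#' substance-specific priors whenever preliminary information exists.
#'
#' @param spec a [model_spec()].
#' @return named list; per parameter a list
#'   `list(dist = "lnorm", meanlog =, sdlog =)`.
#' @export
default_priors <- function(spec) {
  nm <- free_param_names(spec, include_hb = TRUE)
  pr <- lapply(nm, function(p) {
    if (p == "hb") list(dist = "lnorm", meanlog = log(0.02), sdlog = 1.5)
    else if (p == "beta") list(dist = "lnorm", meanlog = log(2), sdlog = 1)
    else list(dist = "lnorm", meanlog = 0, sdlog = 2)
  })
  setNames(pr, nm)
}

prior_logdens <- function(priors, theta_nat) {
  s <- 0
  for (p in names(theta_nat)) {
    pr <- priors[[p]]
    if (is.null(pr)) stop("no prior supplied for parameter ", p)
    s <- s + switch(pr$dist,
      lnorm = dlnorm(theta_nat[[p]], pr$meanlog, pr$sdlog, log = TRUE),
      unif = {
        x <- theta_nat[[p]]
        if (x < pr$min || x > pr$max) -Inf else -log(pr$max - pr$min)
      },
      stop("unsupported prior distribution: ", pr$dist))
  }
  s
}

prior_draw <- function(priors, nm) {
  v <- vapply(nm, function(p) {
    pr <- priors[[p]]
    switch(pr$dist,
      lnorm = rlnorm(1, pr$meanlog, pr$sdlog),
      unif = runif(1, pr$min, pr$max),
      stop("unsupported prior distribution: ", pr$dist))
  }, numeric(1L))
  setNames(v, nm)
}

#' Sampler and optimiser settings
#'
#' @param n_chains number of MCMC chains (default 16).
#' @param n_warmup adaptation iterations discarded per chain (default
#'   2000).
#' @param n_draws retained posterior draws per chain (default 2000).
#' @param n_starts multi-start count for the maximum-likelihood mode.
#' @param target_accept target Metropolis acceptance rate.
#' @param seed integer seed recorded with the result; all randomness in
#'   [calibrate()] derives from it.
#' @return list of settings.
#' @export
calibration_settings <- function(n_chains = 16L, n_warmup = 2000L,
                                 n_draws = 2000L, n_starts = 8L,
                                 target_accept = 0.25, seed = 1L) {
  list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
       n_draws = as.integer(n_draws), n_starts = as.integer(n_starts),
       target_accept = target_accept, seed = as.integer(seed))
}

#' Calibrate a model variant to survival data
#'
#' Bayesian calibration by adaptive random-walk Metropolis sampling on
#' the log-parameter scale (proposal covariance adapted to the chain
#' history during warm-up, scaled towards the target acceptance rate),
#' or penalised maximum likelihood (`method = "ml"`, multi-start
#' L-BFGS-B on log-parameters from prior draws).  All free parameters
#' have positive support and are sampled as logs; the Jacobian is
#' included in the posterior density.
#'
#' Per chain, the mean log-likelihood over its draws and every
#' parameter's sample standard deviation are recorded; these feed the
#' pseudolocal-minimum filter [filter_chains()].  The returned quantiles
#' are computed over the draws of the kept chains only.
#'
#' @param spec a [model_spec()].
#' @param dataset a [survival_dataset()].
#' @param priors named list of priors as in [default_priors()].
#' @param settings a [calibration_settings()] list.
#' @param method `"mcmc"` (default) or `"ml"`.
#' @return An object of class `bg_calibration`: list with `draws`
#'   (array draws x parameters x chains), `loglik` (matrix draws x
#'   chains), `chain_stats` (per chain mean log-likelihood, minimum
#'   parameter sd, acceptance rate), `kept_chains`, `quantiles`,
#'   `map` / `mle` point estimates, `spec`, `priors`, `settings`.
#' @seealso [filter_chains()], [posterior_quantiles()]
#' @export
calibrate <- function(spec, dataset, priors = default_priors(spec),
                      settings = calibration_settings(),
                      method = c("mcmc", "ml")) {
  method <- match.arg(method)
  packed <- pack_dataset(dataset, spec)
  nm <- free_param_names(spec, include_hb = TRUE)
  npar <- length(nm)
  logpost <- function(theta) {  # theta on log scale
    nat <- setNames(exp(theta), nm)
    ll <- loglik_packed(spec, vector_to_params(spec, nat), packed)
    lp <- prior_logdens(priors, as.list(nat)) + sum(theta)  # + Jacobian
    c(post = ll + lp, ll = ll)
  }
  set.seed(settings$seed)

  if (method == "ml") {
    fits <- lapply(seq_len(settings$n_starts), function(s) {
      th0 <- log(prior_draw(priors, nm))
      opt <- tryCatch(
        optim(th0, function(th) -logpost(th)[["post"]], method = "L-BFGS-B",
              lower = rep(-15, npar), upper = rep(15, npar),
              control = list(maxit = 500)),
        error = function(e) list(value = Inf, par = th0))
      opt
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
    est <- setNames(exp(best$par), nm)
    ll <- loglik_packed(spec, vector_to_params(spec, est), packed)
    return(structure(list(method = "ml", mle = est, loglik_hat = ll,
                          spec = spec, priors = priors,
                          settings = settings,
                          converged = is.finite(best$value)),
                     class = "bg_calibration"))
  }

  nch <- settings$n_chains
  nw <- settings$n_warmup
  nd <- settings$n_draws
  draws <- array(NA_real_, dim = c(nd, npar, nch),
                 dimnames = list(NULL, nm, NULL))
  ll_mat <- matrix(NA_real_, nd, nch)
  accept <- numeric(nch)
  for (ch in seq_len(nch)) {
    th <- log(prior_draw(priors, nm))
    cur <- logpost(th)
    tries <- 0
    while (!is.finite(cur[["post"]]) && tries < 50) {
      th <- log(prior_draw(priors, nm))
      cur <- logpost(th)
      tries <- tries + 1
    }
    scale <- 0.1
    cov_chol <- diag(npar)
    hist_mat <- matrix(NA_real_, nw, npar)
    nacc <- 0
    for (it in seq_len(nw + nd)) {
      prop <- th + scale * as.vector(cov_chol %*% rnorm(npar))
      cand <- logpost(prop)
      ok <- is.finite(cand[["post"]]) &&
        log(runif(1)) < cand[["post"]] - cur[["post"]]
      if (ok) { th <- prop; cur <- cand }
      if (it <= nw) {
        hist_mat[it, ] <- th
        # Robbins-Monro scale adaptation towards the target rate
        scale <- scale * exp((as.numeric(ok) - settings$target_accept) /
                               sqrt(it))
        if (it %% 100 == 0 && it >= 200) {
          S <- stats::cov(hist_mat[max(1, it - 499):it, , drop = FALSE])
          ch_try <- tryCatch(chol(S + diag(1e-8, npar)),
                             error = function(e) NULL)
          if (!is.null(ch_try)) cov_chol <- t(ch_try)
        }
      } else {
        draws[it - nw, , ch] <- exp(th)
        ll_mat[it - nw, ch] <- cur[["ll"]]
        nacc <- nacc + as.numeric(ok)
      }
    }
    accept[ch] <- nacc / nd
  }
  chain_stats <- data.frame(
    chain = seq_len(nch),
    mean_loglik = colMeans(ll_mat),
    min_param_sd = apply(draws, 3, function(m) min(apply(m, 2, sd))),
    accept_rate = accept)
  res <- structure(list(method = "mcmc", draws = draws, loglik = ll_mat,
                        chain_stats = chain_stats,
                        kept_chains = rep(TRUE, nch),
                        spec = spec, priors = priors, settings = settings),
                   class = "bg_calibration")
  res <- filter_chains(res)
  if (mean(res$chain_stats$accept_rate[res$kept_chains]) < 0.05)
    warning("very low Metropolis acceptance rate; ",
            "the sampler may not have converged")
  res
}

#' Drop chains stuck on pseudolocal minima
#'
#' MCMC chains occasionally get stuck during warm-up with near-zero
#' parameter variance and clearly worse likelihoods.  A chain is dropped
#' when (a) any parameter's sample standard deviation is at or below
#' `sd_min` (default `1e-6`), or (b) its mean log-likelihood is more
#' than 100% worse than the best chain's (operationalised on the
#' negative log-likelihood scale: worse than `worse_factor` (default 2)
#' times the best chain's mean log-likelihood).  The best chain is
#' always retained, and quantiles are recomputed over the kept chains.
#'
#' @param result a `bg_calibration` from [calibrate()] (MCMC mode).
#' @param sd_min minimum tolerated per-parameter sample sd.
#' @param worse_factor multiplier on the best mean log-likelihood
#'   defining "100% worse".
#' @return the calibration with updated `kept_chains` and `quantiles`.
#' @export
filter_chains <- function(result, sd_min = 1e-6, worse_factor = 2) {
  stopifnot(inherits(result, "bg_calibration"),
            identical(result$method, "mcmc"))
  st <- result$chain_stats
  best <- max(st$mean_loglik)
  ok_sd <- st$min_param_sd > sd_min
  # "less than 100% worse": |mean logL| below worse_factor * |best|
  thr <- if (best < 0) worse_factor * best else best - abs(best) *
    (worse_factor - 1) - .Machine$double.eps
  ok_ll <- st$mean_loglik >= thr
  keep <- ok_sd & ok_ll
  if (!any(keep)) keep[which.max(st$mean_loglik)] <- TRUE
  result$kept_chains <- keep
  result$quantiles <- posterior_quantiles(result)
  result
}

#' Posterior quantiles over the kept chains
#'
#' @param result a `bg_calibration` (MCMC mode).
#' @param probs quantile levels; default 2.5%, 50%, 97.5%.
#' @return data frame: one row per parameter with the requested
#'   quantiles.
#' @export
posterior_quantiles <- function(result, probs = c(0.025, 0.5, 0.975)) {
  stopifnot(inherits(result, "bg_calibration"),
            identical(result$method, "mcmc"))
  keep <- which(result$kept_chains)
  nm <- dimnames(result$draws)[[2]]
  pooled <- do.call(rbind, lapply(keep, function(ch) result$draws[, , ch]))
  q <- t(apply(pooled, 2, quantile, probs = probs, names = FALSE))
  out <- data.frame(parameter = nm, q)
  names(out)[-1L] <- paste0("q", probs * 100)
  rownames(out) <- NULL
  out
}

#' Point-estimate parameter set of a calibration
#'
#' The marginal posterior median over the kept chains' draws, mapped
#' back to a [param_set()]; for ML calibrations, the maximum-likelihood
#' estimate.  The median is used rather than the mean because the
#' likelihood-based chain filter deliberately tolerates chains up to
#' 100% worse than the best one, and a retained secondary mode can pull
#' the mean of a skewed positive-support posterior far from the bulk of
#' the mass while leaving the median untouched.
#'
#' @param result a `bg_calibration`.
#' @return a [param_set()].
#' @export
point_estimate <- function(result) {
  stopifnot(inherits(result, "bg_calibration"))
  nm_spec <- result$spec
  if (identical(result$method, "ml"))
    return(vector_to_params(nm_spec, result$mle))
  keep <- which(result$kept_chains)
  pooled <- do.call(rbind, lapply(keep, function(ch) result$draws[, , ch]))
  vector_to_params(nm_spec, apply(pooled, 2, stats::median))
}

#' @export
print.bg_calibration <- function(x, ...) {
  if (identical(x$method, "ml")) {
    cat("<bg_calibration> maximum likelihood, logL =",
        format(x$loglik_hat, digits = 6), "\n")
    print(x$mle)
  } else {
    cat(sprintf("<bg_calibration> MCMC: %d/%d chains kept, %d draws each\n",
                sum(x$kept_chains), length(x$kept_chains),
                nrow(x$draws)))
    print(x$quantiles, row.names = FALSE)
  }
  invisible(x)
}

#' Export posterior draws and summary to CSV
#'
#' @param result a `bg_calibration` (MCMC mode).
#' @param draws_path,summary_path output CSV paths (`NULL` to skip one).
#' @return invisibly, the summary data frame.
#' @export
export_calibration <- function(result, draws_path = NULL,
                               summary_path = NULL) {
  stopifnot(inherits(result, "bg_calibration"),
            identical(result$method, "mcmc"))
  nm <- dimnames(result$draws)[[2]]
  if (!is.null(draws_path)) {
    tall <- do.call(rbind, lapply(seq_len(dim(result$draws)[3]), function(ch) {
      df <- as.data.frame(result$draws[, , ch])
      names(df) <- nm
      cbind(chain = ch, draw = seq_len(nrow(df)), df)
    }))
    write.csv(tall, draws_path, row.names = FALSE)
  }
  summ <- merge(result$quantiles,
                data.frame(parameter = nm), by = "parameter", sort = FALSE)
  if (!is.null(summary_path)) {
    ks <- result$chain_stats
    ks$kept <- result$kept_chains
    write.csv(summ, summary_path, row.names = FALSE)
    write.csv(ks, sub("(\\.csv)?$", "_chains.csv", summary_path,
                      perl = TRUE), row.names = FALSE)
  }
  invisible(summ)
}
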