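#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * logL` with `k` free parameters, `n` data
#' points and the natural-log likelihood `logL`; lower is better.  BIC
#' values are only comparable between models fitted to the *same*
#' dataset (likelihoods are dataset-specific and unnormalised), which is
#' why [variant_metrics()] ties every BIC to a dataset label and
#' [choose_variant()] refuses to rank across labels.
#'
#' Here `n` is the number of survival observations after replicate
#' summation (time points summed over treatments, excluding the `t = 0`
#' start counts), and `logL` is evaluated at the posterior-median
#' parameters (Bayesian mode, see [point_estimate()]) or the maximum
#' (ML mode).
#'
#' @param log_likelihood natural-log likelihood of the fitted model.
#' @param k number of free parameters ([n_free_parameters()]).
#' @param n number of data points.
#' @return scalar BIC.
#' @examples
#' bic(-50, k = 4, n = 100)  # 4*ln(100) + 100
#' @export
bic <- function(log_likelihood, k, n) {
  if (n < 1 || k < 1) stop("need n >= 1 and k >= 1")
  k * log(n) - 2 * log_likelihood
}

#' Normalised root-mean-square error of survivor counts
#'
#' `NRMSE = sqrt(mean((y - yhat)^2)) / mean(y)`: the RMSE between
#' observed and predicted survivor counts normalised by the mean
#' observed count, comparable across models and datasets; values near
#' zero indicate a good fit.
#'
#' @param observed observed survivor counts.
#' @param predicted predicted survivor counts.
#' @return NRMSE as a fraction (multiply by 100 for %).
#' @examples
#' nrmse(c(10, 10), c(10, 8))  # 0.1 * sqrt(2)
#' @export
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (length(observed) < 1L) stop("need at least one observation")
  ybar <- mean(observed)
  if (ybar <= 0) stop("mean observed count must be positive")
  sqrt(mean((observed - predicted)^2)) / ybar
}

#' Parameter uncertainty index
#'
#' Mean, over the free parameters excluding the background hazard, of
#' `log10(Q97.5 / Q2.5)` of the posterior quantiles.  Low values
#' indicate well-identified parameters; high PUI with a good NRMSE
#' hints at parameter correlations (different parameter combinations
#' giving comparable fits).
#'
#' @param q2.5,q97.5 positive vectors of posterior quantiles for the
#'   non-`hb` parameters, aligned.
#' @return scalar PUI `>= 0`.
#' @examples
#' pui(c(1, 1), c(10, 100))  # mean(1, 2) = 1.5
#' @export
pui <- function(q2.5, q97.5) {
  if (length(q2.5) != length(q97.5) || length(q2.5) < 1L)
    stop("need aligned, non-empty quantile vectors")
  if (any(q2.5 <= 0) || any(q97.5 <= 0))
    stop("quantiles must be positive")
  mean(log10(q97.5 / q2.5))
}

#' Metrics for one calibrated variant
#'
#' Convenience wrapper computing `k`, `n`, BIC, NRMSE and PUI for a
#' calibration on its dataset.
#'
#' @param result a `bg_calibration`.
#' @param dataset the [survival_dataset()] it was calibrated to.
#' @param dataset_id label identifying the dataset; BIC comparisons are
#'   restricted to identical labels.
#' @return one-row data frame of class `bg_metrics`.
#' @export
variant_metrics <- function(result, dataset, dataset_id = "data") {
  spec <- result$spec
  params <- point_estimate(result)
  k <- n_free_parameters(spec$combination, spec$death, spec$n_routes,
                         include_hb = TRUE)
  pc <- predicted_counts(spec, params, dataset)
  pc <- pc[pc$time_d > 0, ]
  n <- nrow(pc)
  ll <- log_likelihood(spec, params, dataset)
  pv <- NA_real_
  if (identical(result$method, "mcmc")) {
    q <- result$quantiles
    q <- q[q$parameter != "hb", ]
    pv <- pui(q$q2.5, q$q97.5)
  }
  out <- data.frame(
    variant = paste0(spec$combination, "-", spec$death),
    dataset_id = dataset_id, k = k, n = n,
    loglik = ll, bic = bic(ll, k, n),
    nrmse = nrmse(pc$observed, pc$predicted), pui = pv)
  class(out) <- c("bg_metrics", "data.frame")
  out
}

#' Rank model variants and pick one
#'
#' Selection procedure across calibrated variants of *one* dataset:
#' goodness of fit first (NRMSE, with BIC asked to agree), parsimony
#' and identifiability as tie-breakers.  Concretely: variants whose
#' NRMSE lies within `nrmse_tol` of the best (or whose NRMSE intervals
#' overlap the best's, when intervals are supplied) are "comparable";
#' among comparable variants the one with the lowest PUI is preferred,
#' remaining ties go to fewer free parameters, then lower BIC.  If no
#' variant is comparable to the best-NRMSE variant, that variant is
#' chosen when it also has the lowest BIC; otherwise the variant with
#' the best mean rank of NRMSE and BIC wins.  A text rationale records
#' each applied rule.
#'
#' @param metrics data frame with columns `variant`, `dataset_id`, `k`,
#'   `bic`, `nrmse`, `pui` (e.g. `rbind()` of [variant_metrics()] rows);
#'   optional `nrmse_lo` / `nrmse_hi` uncertainty intervals.
#' @param nrmse_tol absolute NRMSE tolerance within which variants count
#'   as comparable (default 0.05, i.e. 5 percentage points).
#' @return list with `chosen` (variant id), `ranking` (data frame) and
#'   `rationale` (character).
#' @export
choose_variant <- function(metrics, nrmse_tol = 0.05) {
  stopifnot(nrow(metrics) >= 2L)
  if (length(unique(metrics$dataset_id)) > 1L)
    stop("BIC-based ranking across different datasets is not meaningful; ",
         "choose_variant() requires a single dataset_id")
  m <- as.data.frame(metrics)
  rationale <- character()
  best_nr <- which.min(m$nrmse)
  has_int <- all(c("nrmse_lo", "nrmse_hi") %in% names(m)) &&
    !anyNA(m$nrmse_lo) && !anyNA(m$nrmse_hi)
  comparable <- if (has_int) {
    m$nrmse_lo <= m$nrmse_hi[best_nr] & m$nrmse_hi >= m$nrmse_lo[best_nr]
  } else {
    m$nrmse <= m$nrmse[best_nr] + nrmse_tol
  }
  if (sum(comparable) == 1L) {
    pick <- best_nr
    rationale <- c(rationale, sprintf(
      "%s has the lowest NRMSE (%.3f) and no other variant is comparable.",
      m$variant[best_nr], m$nrmse[best_nr]))
    if (m$bic[best_nr] > min(m$bic)) {
      # fit metrics disagree: fall back to mean rank of NRMSE and BIC
      score <- rank(m$nrmse) + rank(m$bic)
      pick <- which.min(score + rank(m$k) / 1e3)
      rationale <- c(rationale, sprintf(
        "BIC disagrees (lowest: %s); choosing the best joint NRMSE+BIC rank: %s.",
        m$variant[which.min(m$bic)], m$variant[pick]))
    }
  } else {
    cand <- which(comparable)
    rationale <- c(rationale, sprintf(
      "Comparable fit (NRMSE within %s of the best): %s.",
      if (has_int) "overlapping intervals" else format(nrmse_tol),
      paste(m$variant[cand], collapse = ", ")))
    puiv <- ifelse(is.na(m$pui), Inf, m$pui)  # no PUI: rank by k, then BIC
    ord <- cand[order(puiv[cand], m$k[cand], m$bic[cand], m$nrmse[cand])]
    pick <- ord[1L]
    if (!anyNA(m$pui[cand]) && length(unique(m$pui[cand])) > 1L)
      rationale <- c(rationale, sprintf(
        "Preferring the lowest parameter uncertainty: %s (PUI %.3f).",
        m$variant[pick], m$pui[pick]))
    if (anyNA(m$pui[cand]))
      rationale <- c(rationale,
                     "PUI unavailable for some variants; ranked by fewer parameters, then BIC.")
    if (m$k[pick] == min(m$k[cand]) && length(unique(m$k[cand])) > 1L)
      rationale <- c(rationale, sprintf(
        "%s also uses the fewest free parameters (k = %d).",
        m$variant[pick], m$k[pick]))
  }
  ranking <- m[order(seq_len(nrow(m)) != pick, m$nrmse), ]
  list(chosen = m$variant[pick], ranking = ranking,
       rationale = paste(rationale, collapse = " "))
}
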