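#' Convert an acute-oral dose to a food concentration
#'
#' Acute oral honeybee tests report the consumed dose per bee (ug
#' a.i./bee), while chronic oral tests report the concentration of the
#' contaminated food (mg a.i./kg food).  The food concentration is the
#' unit that is comparable across oral designs, because it is directly
#' related to the concentration in the gut and independent of exposure
#' time.  Assuming a food consumption of `consumption_mg_per_bee`
#' (regulatory tests aim at ~20 mg of food per bee during the feeding
#' phase), a consumed dose converts as
#' `dose [ug/bee] / consumption [mg/bee] * 1000 = concentration [mg/kg]`.
#'
#' @param dose_ug_per_bee consumed dose, ug a.i./bee; `>= 0`.
#' @param consumption_mg_per_bee food consumed during the feeding phase,
#'   mg/bee; default 20.
#' @return food concentration in mg a.i./kg food.
#' @examples
#' convert_acute_oral_dose(0.0336)  # 1.68 mg a.i./kg food
#' convert_acute_oral_dose(0.136)   # 6.80
#' @export
convert_acute_oral_dose <- function(dose_ug_per_bee,
                                    consumption_mg_per_bee = 20) {
  if (any(consumption_mg_per_bee <= 0))
    stop("consumption must be positive")
  if (any(dose_ug_per_bee < 0)) stop("dose must be non-negative")
  # ug/mg == g/kg, so x1000 for mg/kg
  dose_ug_per_bee / consumption_mg_per_bee * 1000
}

#' Inverse of [convert_acute_oral_dose()]
#' @param conc_mg_per_kg food concentration, mg a.i./kg food.
#' @inheritParams convert_acute_oral_dose
#' @return consumed dose in ug a.i./bee.
#' @export
convert_food_conc_to_dose <- function(conc_mg_per_kg,
                                      consumption_mg_per_bee = 20) {
  if (any(consumption_mg_per_bee <= 0))
    stop("consumption must be positive")
  conc_mg_per_kg * consumption_mg_per_bee / 1000
}

#' Discretise a test design into an exposure profile
#'
#' Raw regulatory test designs are turned into piecewise-constant
#' exposure profiles on a 1-hour grid (the smallest exposure time unit;
#' exposures shorter than an hour, such as a topical droplet, are
#' modelled as lasting one hour so that an instantaneous dose carries a
#' well-defined area under the curve):
#'
#' * `acute_contact`: the topical dose as a single 1-hour pulse
#'   `[0, 1/24 d)` on route 1, unit ug a.i./bee.
#' * `acute_oral`: the dose converted to a food concentration
#'   ([convert_acute_oral_dose()]), constant over the feeding window
#'   `[0, feeding_duration_h]` (at most 6 h, rounded up to whole hours),
#'   zero afterwards; route 2, unit mg a.i./kg food.
#' * `chronic_oral`: the food concentration, constant over the whole
#'   test period (daily replenishment is modelled as constant exposure);
#'   route 2, unit mg a.i./kg food.
#'
#' @param design one of `"acute_contact"`, `"acute_oral"`,
#'   `"chronic_oral"`.
#' @param dose_or_conc the design's native exposure value: ug a.i./bee
#'   for acute designs, mg a.i./kg food for chronic oral.
#' @param feeding_duration_h feeding window for acute oral tests, hours;
#'   default (and maximum) 6.
#' @param test_duration_d test length in days (chronic oral exposure
#'   covers all of it).
#' @param consumption_mg_per_bee food consumption assumed for the
#'   acute-oral dose conversion.
#' @return an [exposure_profile()] (route 1 for contact, route 2 for
#'   oral designs).
#' @examples
#' discretize_design("acute_contact", 0.262)
#' discretize_design("chronic_oral", 18.0, test_duration_d = 10)
#' @export
discretize_design <- function(design = c("acute_contact", "acute_oral",
                                         "chronic_oral"),
                              dose_or_conc,
                              feeding_duration_h = 6,
                              test_duration_d = if (design == "chronic_oral")
                                10 else 2,
                              consumption_mg_per_bee = 20) {
  design <- match.arg(design)
  if (dose_or_conc < 0) stop("exposure value must be non-negative")
  switch(design,
    acute_contact = exposure_profile(
      1L, "ug a.i./bee", 0, HOUR, dose_or_conc),
    acute_oral = {
      if (is.na(feeding_duration_h)) feeding_duration_h <- 6
      if (feeding_duration_h <= 0 || feeding_duration_h > 6)
        stop("acute-oral feeding duration must be in (0, 6] hours")
      hrs <- ceiling(feeding_duration_h)  # snap to the 1-h grid
      conc <- convert_acute_oral_dose(dose_or_conc, consumption_mg_per_bee)
      exposure_profile(2L, "mg a.i./kg food", 0, hrs * HOUR, conc)
    },
    chronic_oral = {
      if (test_duration_d <= 0) stop("test duration must be positive")
      exposure_profile(2L, "mg a.i./kg food", 0, test_duration_d,
                       dose_or_conc)
    })
}

#' Sum survival counts over replicates of one treatment
#'
#' Replicate batches of the same treatment are pooled by summing the
#' survivor counts at every observation time.  Because the conditional
#' binomial likelihood of the pooled record equals the sum of the
#' per-replicate log-likelihoods up to a parameter-independent
#' combinatorial constant, pooling reduces the number of likelihood
#' evaluations without affecting inference.
#'
#' @param records list of records; each is a list with `times` (shared
#'   observation grid, days) and `n_alive` (survivor counts).
#' @return one record with the summed counts (all other fields taken
#'   from the first record).
#' @examples
#' a <- list(times = 0:2, n_alive = c(10, 8, 7))
#' b <- list(times = 0:2, n_alive = c(10, 9, 9))
#' sum_replicates(list(a, b))$n_alive  # 20 17 16
#' @export
sum_replicates <- function(records) {
  stopifnot(length(records) >= 1L)
  t0 <- records[[1L]]$times
  for (r in records) {
    if (!isTRUE(all.equal(r$times, t0)))
      stop("replicates must share the same observation times")
    if (is.unsorted(r$times) || any(diff(r$n_alive) > 0))
      stop("survivor counts must be non-increasing in time")
  }
  out <- records[[1L]]
  out$n_alive <- Reduce(`+`, lapply(records, `[[`, "n_alive"))
  out
}

#' Flag discordant acute-oral tests
#'
#' Within each compound, an acute-oral test is excluded when its 48-h
#' LD50 differs by at least `factor` (default 8) from *every* other
#' acute-oral test of that compound, and its implied food-concentration
#' LC50 is lower than the compound's chronic 10-day LC50 (an acute test
#' that appears far more sensitive than both the other acute tests and
#' the long-term test is treated as unreliable).
#'
#' @param tests data frame with columns `compound`, `report_no`,
#'   `design`, `ld50_48h_ug_bee`, `lc50_chronic_mg_kg` (see
#'   [load_regulatory_tests()]).
#' @param factor fold-difference threshold; default 8.
#' @param require_below_chronic also require the test's LC50 to lie
#'   below the chronic LC50 (default `TRUE`).
#' @param consumption_mg_per_bee consumption used to express acute-oral
#'   LD50s as food concentrations.
#' @return the input with a logical column `excluded`.
#' @examples
#' tab <- load_regulatory_tests()
#' res <- exclude_outlier_tests(tab)
#' sum(res$excluded)      # 3
#' sum(!res$excluded)     # 26
#' @export
exclude_outlier_tests <- function(tests, factor = 8,
                                  require_below_chronic = TRUE,
                                  consumption_mg_per_bee = 20) {
  need <- c("compound", "design", "ld50_48h_ug_bee", "lc50_chronic_mg_kg")
  miss <- setdiff(need, names(tests))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  tests$excluded <- FALSE
  for (cp in unique(tests$compound)) {
    ao <- which(tests$compound == cp & tests$design == "acute_oral")
    if (length(ao) < 2L) next
    ld <- tests$ld50_48h_ug_bee[ao]
    if (anyNA(ld)) stop("acute-oral tests of ", cp, " lack a 48-h LD50")
    chronic <- tests$lc50_chronic_mg_kg[
      tests$compound == cp & tests$design == "chronic_oral"]
    chronic <- chronic[!is.na(chronic)]
    for (j in seq_along(ao)) {
      others <- ld[-j]
      ratio <- pmax(ld[j] / others, others / ld[j])
      far <- all(ratio >= factor)
      below <- if (!require_below_chronic) TRUE else {
        length(chronic) >= 1L &&
          convert_acute_oral_dose(ld[j], consumption_mg_per_bee) <
            min(chronic)
      }
      if (far && below) tests$excluded[ao[j]] <- TRUE
    }
  }
  tests
}

#' Bundled honeybee regulatory test summary
#'
#' A summary table of 29 standard honeybee (*Apis mellifera*) regulatory
#' tests for five insecticides (deltamethrin, ethiprole, imidacloprid,
#' tetraniliprole, thiacloprid) from public Bayer transparency study
#' reports: acute contact (48-h topical LD50, ug a.i./bee), acute oral
#' (48-h LD50, ug a.i./bee) and chronic oral (10-day LD50 in
#' ug a.i./bee/day and LC50 in mg a.i./kg food) designs.
#'
#' @return data frame with columns `compound`, `report_no`, `design`,
#'   `ld50_48h_ug_bee`, `ld50_10d_ug_bee_day`, `lc50_chronic_mg_kg`,
#'   `test_duration_d`, `feeding_duration_h`.
#' @export
load_regulatory_tests <- function() {
  read.csv(system.file("extdata", "honeybee_regulatory_tests.csv",
                       package = "bufferguts"),
           stringsAsFactors = FALSE)
}
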