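#' Design template for a synthetic honeybee-style test
#'
#' Describes one regulatory-style test design for the synthetic-data
#' generator: acute contact (1-h topical pulse, 2-day observation),
#' acute oral (up to 6-h feeding window, 2-day observation) or chronic
#' oral (constant feeding over 10 days).  Defaults mirror the standard
#' designs: batches of 10 bees, several batches per treatment, daily
#' observations including the test start and end, and a concentration
#' ladder that always includes an unexposed control.
#'
#' @param design `"acute_contact"`, `"acute_oral"` or `"chronic_oral"`.
#' @param levels exposure levels in the design's native unit (ug
#'   a.i./bee for acute contact; mg a.i./kg food for oral designs); a
#'   control (0) is appended when missing.
#' @param n_per_treatment individuals per treatment (default 10, one
#'   batch; use multiples of 10 for several batches).
#' @param obs_times observation times in days; default daily over 2 d
#'   (acute) or 10 d (chronic).
#' @param feeding_duration_h acute-oral feeding window, hours.
#' @return list of class `bg_template`.
#' @export
design_template <- function(design = c("acute_contact", "acute_oral",
                                       "chronic_oral"),
                            levels, n_per_treatment = 10L,
                            obs_times = NULL, feeding_duration_h = 6) {
  design <- match.arg(design)
  if (any(levels < 0)) stop("levels must be non-negative")
  if (!any(levels == 0)) levels <- c(0, levels)
  dur <- if (design == "chronic_oral") 10 else 2
  if (is.null(obs_times)) obs_times <- seq(0, dur)
  if (obs_times[1L] != 0 || max(obs_times) < dur)
    stop("observation times must start at 0 and include the test end")
  structure(list(design = design, levels = sort(unique(levels)),
                 n_per_treatment = as.integer(n_per_treatment),
                 obs_times = as.numeric(obs_times),
                 test_duration_d = dur,
                 feeding_duration_h = feeding_duration_h),
            class = "bg_template")
}

# route profiles (contact = 1, oral = 2) for one level of a template
template_profiles <- function(template, level, n_routes = 2L) {
  empty <- function(route, unit) exposure_profile(route, unit, numeric(),
                                                  numeric(), numeric())
  if (template$design == "acute_contact") {
    p1 <- if (level > 0) discretize_design("acute_contact", level)
          else empty(1L, "ug a.i./bee")
    p2 <- empty(2L, "mg a.i./kg food")
  } else {
    p1 <- empty(1L, "ug a.i./bee")
    p2 <- if (level > 0) {
      if (template$design == "acute_oral") {
        # template levels are food concentrations already
        exposure_profile(2L, "mg a.i./kg food", 0,
                         ceiling(template$feeding_duration_h) * HOUR, level)
      } else {
        discretize_design("chronic_oral", level,
                          test_duration_d = template$test_duration_d)
      }
    } else empty(2L, "mg a.i./kg food")
  }
  if (n_routes == 1L) list(p1) else list(p1, p2)
}

#' Generate a synthetic survival dataset from known parameters
#'
#' Builds the exposure profile of every template level via the same
#' discretisation rules as the real designs, simulates the model
#' survival curve, and draws the deaths in each observation interval by
#' sequential conditional binomial sampling: given `n` survivors at
#' `t_(j-1)`, the survivors at `t_j` are
#' `Binomial(n, S(t_j) / S(t_(j-1)))`.  Controls experience only the
#' background hazard.
#'
#' @param spec a two-route (contact + oral) or single-route
#'   [model_spec()].
#' @param true_params a [param_set()] used as ground truth.
#' @param templates list of [design_template()]s.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a [survival_dataset()]; each treatment carries `design`,
#'   `level` and the generating seed in its fields.
#' @export
generate_dataset <- function(spec, true_params, templates, seed = 1L) {
  stopifnot(inherits(spec, "bg_spec"))
  if (inherits(templates, "bg_template")) templates <- list(templates)
  set.seed(as.integer(seed))
  treatments <- list()
  for (tp in templates) {
    for (lev in tp$levels) {
      profiles <- template_profiles(tp, lev, spec$n_routes)
      sim <- simulate_bufferguts(spec, true_params, profiles,
                                 times = tp$obs_times)
      S <- sim$S
      n <- tp$n_per_treatment
      alive <- integer(length(S))
      alive[1L] <- n
      for (j in seq_along(S)[-1L]) {
        p <- if (S[j - 1L] <= 0) 0 else min(1, S[j] / S[j - 1L])
        alive[j] <- rbinom(1L, alive[j - 1L], p)
      }
      treatments[[length(treatments) + 1L]] <- list(
        profiles = profiles, times = tp$obs_times, n_alive = alive,
        id = sprintf("%s_%g", tp$design, lev),
        design = tp$design, level = lev, seed = seed)
    }
  }
  survival_dataset(treatments, n_routes = spec$n_routes)
}

#' Level producing ~50% mortality at the end of a design
#'
#' Root-finds the exposure level of a template at which the model
#' survival at the test end equals `target`; used to centre the default
#' geometric concentration ladders the way dose-ranging pretests do.
#'
#' @inheritParams generate_dataset
#' @param template a [design_template()].
#' @param target survival probability at the test end (default 0.5).
#' @return the exposure level (native design unit).
#' @export
find_level50 <- function(spec, true_params, template, target = 0.5) {
  f <- function(level) {
    pr <- template_profiles(template, level, spec$n_routes)
    sim <- simulate_bufferguts(spec, true_params, pr,
                               times = c(0, template$test_duration_d))
    sim$S[2L] - target
  }
  lo <- 1e-6; hi <- 1
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 4
  while (f(lo) < 0 && lo > 1e-12) lo <- lo / 4
  uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Default three-design synthetic study
#'
#' One acute-contact, one acute-oral and one chronic-oral template with
#' geometric concentration ladders (factor `ladder_factor`, default 2.5)
#' centred on the level giving ~50% mortality at each test's end under
#' the true parameters, `n_levels` exposed levels plus a control.
#'
#' @inheritParams generate_dataset
#' @param n_levels exposed levels per design (default 5).
#' @param n_per_treatment individuals per treatment.
#' @param ladder_factor geometric spacing of the ladder.
#' @return list of [design_template()]s.
#' @export
default_study_templates <- function(spec, true_params, n_levels = 5L,
                                    n_per_treatment = 40L,
                                    ladder_factor = 2.5) {
  mk <- function(design) {
    base <- design_template(design, levels = 1,
                            n_per_treatment = n_per_treatment)
    l50 <- find_level50(spec, true_params, base)
    ladder <- l50 * ladder_factor^(seq_len(n_levels) -
                                     (n_levels + 1) / 2)
    design_template(design, levels = ladder,
                    n_per_treatment = n_per_treatment)
  }
  lapply(c("acute_contact", "acute_oral", "chronic_oral"), mk)
}

#' Validation scenario grid: contact pulse crossed with oral windows
#'
#' The proposed terrestrial validation design: a single topical contact
#' pulse at `t = 0` combined with oral exposure windows of 1 and 2 days
#' starting after a set of delays, so that the model is probed on
#' exposure timings not used for calibration.  Scenarios with
#' `contact_dose = 0` or `oral_level = 0` give the single-route
#' references; the control (both zero) shows pure background survival
#' `exp(-hb t)`.
#'
#' @param contact_dose contact pulse height, route-1 units.
#' @param oral_level oral window level, route-2 units.
#' @param oral_durations oral window lengths in days (default `c(1, 2)`).
#' @param delays start of the oral window after the contact pulse, days.
#' @param horizon scenario length, days.
#' @return data frame of scenarios (one per row) with class
#'   `bg_scenarios`.
#' @export
make_validation_suite <- function(contact_dose, oral_level,
                                  oral_durations = c(1, 2),
                                  delays = c(0, 1, 2, 4),
                                  horizon = 10) {
  grid <- expand.grid(oral_start = delays, oral_duration = oral_durations)
  grid <- grid[grid$oral_start + grid$oral_duration <= horizon, ]
  out <- rbind(
    data.frame(scenario = "control", contact_dose = 0, oral_level = 0,
               oral_start = 0, oral_duration = 0),
    data.frame(scenario = "contact_only", contact_dose = contact_dose,
               oral_level = 0, oral_start = 0, oral_duration = 0),
    data.frame(scenario = sprintf("contact+oral_%gd_delay%g",
                                  grid$oral_duration, grid$oral_start),
               contact_dose = contact_dose, oral_level = oral_level,
               oral_start = grid$oral_start,
               oral_duration = grid$oral_duration))
  out$horizon <- horizon
  class(out) <- c("bg_scenarios", "data.frame")
  out
}

#' Simulate every scenario of a validation suite
#'
#' @param spec,params model and parameters (two-route).
#' @param scenarios a [make_validation_suite()] data frame.
#' @param dt output resolution, days.
#' @return data frame: `scenario`, `time_d`, `S`.
#' @export
simulate_validation_suite <- function(spec, params, scenarios, dt = 1 / 24) {
  out <- lapply(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    tr <- predict_scenario(spec, params, sc$contact_dose, sc$oral_level,
                           sc$oral_start, sc$oral_duration,
                           horizon = sc$horizon, dt = dt)
    data.frame(scenario = sc$scenario, time_d = tr$time_d, S = tr$S)
  })
  do.call(rbind, out)
}

#' Write a miniature synthetic study to disk
#'
#' Emits the CSV formats the preprocessing module consumes: an exposure
#' CSV (`exposures.csv`), a survival observation CSV (`survival.csv`)
#' and the generating configuration (`manifest.json`).
#'
#' @inheritParams generate_dataset
#' @param dir output directory (created if missing).
#' @return invisibly, the generated [survival_dataset()].
#' @export
write_synthetic_study <- function(spec, true_params, templates, seed = 1L,
                                  dir = "synthetic_study") {
  ds <- generate_dataset(spec, true_params, templates, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  exp_rows <- list(); surv_rows <- list()
  for (tr in ds$treatments) {
    for (p in tr$profiles) {
      if (!nrow(p$segments)) next
      exp_rows[[length(exp_rows) + 1L]] <- data.frame(
        test_id = tr$design, treatment_id = tr$id, route_id = p$route_id,
        unit = p$unit, t_start_d = p$segments$t_start,
        t_end_d = p$segments$t_end, level = p$segments$level)
    }
    surv_rows[[length(surv_rows) + 1L]] <- data.frame(
      test_id = tr$design, treatment_id = tr$id, time_d = tr$times,
      n_alive = tr$n_alive)
  }
  write.csv(do.call(rbind, exp_rows), file.path(dir, "exposures.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, surv_rows), file.path(dir, "survival.csv"),
            row.names = FALSE)
  manifest <- list(seed = seed, spec = unclass(spec),
                   true_params = unclass(true_params),
                   package_version = as.character(packageVersion("bufferguts")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(ds)
}
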