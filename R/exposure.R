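#' Piecewise-constant exposure profile for one uptake route
#'
#' An exposure profile is the external forcing of the TKTD model for a
#' single uptake route of a single treatment: an ordered set of
#' non-overlapping, half-open time segments `[t_start, t_end)` (days) with
#' a constant non-negative exposure level on each.  Exposure is zero
#' outside the segments.  Route 1 is topical contact by convention; its
#' unit anchors the units of the damage state and of the threshold
#' parameters.
#'
#' @param route_id small positive integer route index (1 = contact).
#' @param unit text label for the exposure unit, e.g. `"ug a.i./bee"` or
#'   `"mg a.i./kg food"`.
#' @param t_start,t_end numeric vectors of segment boundaries in days.
#' @param level numeric vector of non-negative exposure levels, one per
#'   segment.
#'
#' @return An object of class `bg_exposure`: a list with `route_id`,
#'   `unit` and a data frame `segments`.
#' @examples
#' # a 1-hour topical pulse of 0.262 ug a.i./bee
#' exposure_profile(1, "ug a.i./bee", 0, 1 / 24, 0.262)
#' @export
exposure_profile <- function(route_id, unit, t_start, t_end, level) {
  stopifnot(length(route_id) == 1L, route_id >= 1,
            length(t_start) == length(t_end),
            length(level) == length(t_start))
  if (length(t_start)) {
    o <- order(t_start)
    t_start <- t_start[o]; t_end <- t_end[o]; level <- level[o]
    if (any(t_end <= t_start))
      stop("exposure segments must have t_start < t_end")
    if (any(level < 0))
      stop("exposure levels must be non-negative")
    if (length(t_start) > 1L && any(t_start[-1L] < t_end[-length(t_end)]))
      stop("exposure segments must not overlap")
  }
  structure(
    list(route_id = as.integer(route_id), unit = unit,
         segments = data.frame(t_start = as.numeric(t_start),
                               t_end = as.numeric(t_end),
                               level = as.numeric(level))),
    class = "bg_exposure")
}

#' @export
print.bg_exposure <- function(x, ...) {
  cat(sprintf("<bg_exposure> route %d [%s], %d segment(s)\n",
              x$route_id, x$unit, nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Evaluate an exposure profile at given times
#'
#' Segments are half-open `[t_start, t_end)`.
#'
#' @param profile a [exposure_profile()] object.
#' @param times numeric vector of times in days.
#' @return numeric vector of exposure levels.
#' @export
exposure_at <- function(profile, times) {
  out <- numeric(length(times))
  seg <- profile$segments
  for (i in seq_len(nrow(seg))) {
    hit <- times >= seg$t_start[i] & times < seg$t_end[i]
    out[hit] <- seg$level[i]
  }
  out
}

# breakpoints / levels matrix shared by the solver backends:
# returns list(breakpoints, levels) where levels is n_routes x n_intervals
build_forcing <- function(profiles, t_max) {
  n <- length(profiles)
  bks <- c(0, t_max)
  for (p in profiles)
    bks <- c(bks, p$segments$t_start, p$segments$t_end)
  bks <- sort(unique(bks[bks >= 0 & bks <= t_max]))
  if (length(bks) < 2L) bks <- c(0, t_max)
  mids <- (bks[-length(bks)] + bks[-1L]) / 2
  levels <- matrix(0, nrow = n, ncol = length(mids))
  for (i in seq_len(n)) levels[i, ] <- exposure_at(profiles[[i]], mids)
  list(breakpoints = bks, levels = levels)
}

#' Read / write exposure profiles as CSV
#'
#' The on-disk format has one row per segment with columns `test_id`,
#' `treatment_id`, `route_id`, `unit`, `t_start_d`, `t_end_d`, `level`.
#'
#' @param path file path.
#' @return `read_exposure_csv()` returns a nested list: per test, per
#'   treatment, a list of [exposure_profile()] objects (one per route).
#' @export
read_exposure_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("test_id", "treatment_id", "route_id", "unit",
            "t_start_d", "t_end_d", "level")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("exposure CSV is missing column(s): ", paste(miss, collapse = ", "))
  out <- list()
  for (tid in unique(df$test_id)) {
    dt <- df[df$test_id == tid, ]
    out[[as.character(tid)]] <- lapply(
      split(dt, dt$treatment_id),
      function(dtr) lapply(split(dtr, dtr$route_id), function(dr) {
        exposure_profile(dr$route_id[1L], dr$unit[1L],
                         dr$t_start_d, dr$t_end_d, dr$level)
      }))
  }
  out
}

#' @param profiles list of [exposure_profile()] objects.
#' @param test_id,treatment_id identifiers written to the CSV.
#' @rdname read_exposure_csv
#' @export
write_exposure_csv <- function(profiles, path, test_id = "test1",
                               treatment_id = "t1") {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    if (!nrow(p$segments)) return(NULL)
    data.frame(test_id = test_id, treatment_id = treatment_id,
               route_id = p$route_id, unit = p$unit,
               t_start_d = p$segments$t_start, t_end_d = p$segments$t_end,
               level = p$segments$level)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
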