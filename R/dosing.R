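#' Dosing schedule
#'
#' A biologic's PBS dosing pattern: explicit loading doses followed by a fixed
#' steady-state interval. Week offsets are measured from the start of the
#' treatment line; dose calendars restart at week 0 whenever a new line begins.
#'
#' @param loading_dose_weeks integer vector of loading-dose week offsets,
#'   strictly increasing, first element 0.
#' @param steady_interval_weeks positive integer; weeks between doses after the
#'   final loading dose ("every N weeks thereafter").
#' @param loading_dose_units optional numeric vector parallel to
#'   `loading_dose_weeks`: dispense units consumed by each loading dose
#'   (default 1 each). Used where a loading dose is a double dose of the
#'   dispensed strength, e.g. 80 mg adalimumab or 160 mg ixekizumab at week 0.
#' @return object of class `psor_schedule`.
#' @examples
#' dosing_schedule(c(0, 4), 12)                # week 0, 4, then every 12 weeks
#' dosing_schedule(c(0, 1), 2, c(2, 1))        # 80 mg start, then 40 mg q2w
#' @export
dosing_schedule <- function(loading_dose_weeks, steady_interval_weeks,
                            loading_dose_units = NULL) {
  lw <- as.numeric(loading_dose_weeks)
  if (length(lw) == 0L || lw[1] != 0)
    stop("loading_dose_weeks must start at 0", call. = FALSE)
  if (any(diff(lw) <= 0))
    stop("loading_dose_weeks must be strictly increasing", call. = FALSE)
  si <- as.numeric(steady_interval_weeks)
  if (length(si) != 1L || is.na(si) || si < 1)
    stop("steady_interval_weeks must be a single integer >= 1", call. = FALSE)
  if (is.null(loading_dose_units)) loading_dose_units <- rep(1, length(lw))
  lu <- as.numeric(loading_dose_units)
  if (length(lu) != length(lw) || any(lu <= 0))
    stop("loading_dose_units must be positive and parallel to loading_dose_weeks",
         call. = FALSE)
  structure(list(loading_dose_weeks = lw,
                 loading_dose_units = lu,
                 steady_interval_weeks = si),
            class = "psor_schedule")
}

#' @export
print.psor_schedule <- function(x, ...) {
  cat(sprintf("<dosing schedule> weeks %s, then every %g weeks\n",
              paste(x$loading_dose_weeks, collapse = ", "),
              x$steady_interval_weeks))
  invisible(x)
}

#' Dose calendar for a treatment line
#'
#' Expands a schedule into all dose week offsets `t` with `0 <= t < duration_weeks`:
#' the loading doses, then one dose every `steady_interval_weeks` after the final
#' loading dose.
#'
#' @param schedule a [dosing_schedule()].
#' @param duration_weeks non-negative window length (weeks from line start).
#' @return numeric vector of dose week offsets (possibly empty).
#' @examples
#' s <- dosing_schedule(c(0, 1), 2)   # adalimumab-style
#' dose_times(s, 12)                  # 0 1 3 5 7 9 11
#' @export
dose_times <- function(schedule, duration_weeks) {
  stopifnot(inherits(schedule, "psor_schedule"))
  if (length(duration_weeks) != 1L || is.na(duration_weeks) || duration_weeks < 0)
    stop("duration_weeks must be a single non-negative number", call. = FALSE)
  lw <- schedule$loading_dose_weeks
  out <- lw[lw < duration_weeks]
  first_steady <- max(lw) + schedule$steady_interval_weeks
  if (first_steady < duration_weeks) {
    st <- seq(first_steady, duration_weeks, by = schedule$steady_interval_weeks)
    out <- c(out, st[st < duration_weeks])
  }
  out
}

#' Count doses in a half-open interval
#'
#' Number of dose events with offsets in `[start_week, end_week)`. The half-open
#' convention places a dose falling exactly on a review/switch boundary in the
#' following period, so e.g. the ixekizumab week-12 dose is the first
#' maintenance dose.
#'
#' @param schedule a [dosing_schedule()].
#' @param start_week,end_week interval bounds in weeks from line start,
#'   `0 <= start_week <= end_week`.
#' @return integer count of dose events.
#' @export
doses_in_interval <- function(schedule, start_week, end_week) {
  if (start_week < 0 || end_week < start_week)
    stop("need 0 <= start_week <= end_week", call. = FALSE)
  dt <- dose_times(schedule, end_week)
  sum(dt >= start_week)
}

#' Dispense units in a half-open interval
#'
#' Like [doses_in_interval()] but weighting each dose event by its dispense
#' units (loading doses may consume more than one unit of the dispensed
#' strength). This is the quantity multiplied by the per-unit drug cost when
#' accruing acquisition costs.
#'
#' @inheritParams doses_in_interval
#' @return numeric unit count.
#' @export
dose_units_in_interval <- function(schedule, start_week, end_week) {
  if (start_week < 0 || end_week < start_week)
    stop("need 0 <= start_week <= end_week", call. = FALSE)
  lw <- schedule$loading_dose_weeks
  keep <- lw >= start_week & lw < end_week
  units <- sum(schedule$loading_dose_units[keep])
  first_steady <- max(lw) + schedule$steady_interval_weeks
  if (first_steady < end_week) {
    st <- seq(first_steady, end_week, by = schedule$steady_interval_weeks)
    units <- units + sum(st >= start_week & st < end_week)
  }
  units
}
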