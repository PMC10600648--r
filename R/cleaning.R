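#' Pandemic data-collection cutoff dates per site
#'
#' Days after these dates are excluded for the respective sites (restriction
#' declarations: 2020-03-20 in Illinois for the RUSH cohort, 2020-03-23 in
#' Oregon for the OHSU and VA cohorts).
#' @export
covid_cutoffs <- function() {
  c(RUSH = as.Date("2020-03-20"),
    OHSU = as.Date("2020-03-23"),
    VA = as.Date("2020-03-23"))
}

#' Detect sensor-inactive days
#'
#' A day is flagged sensor-inactive for a home when at least one installed
#' sensor emitted zero events over the full calendar day while at least one
#' other sensor of the same home was active (the typical low-battery
#' signature). By default only motion sensors are screened: every room of a
#' lived-in home sees some traffic daily, whereas an egress-door contact is
#' legitimately silent on any day without an entry or exit, so door silence
#' is not evidence of failure.
#'
#' @param ev event data.frame.
#' @param sensors optional data.frame `home_id,sensor_id` of installed
#'   sensors; defaults to every sensor ever seen per home (of the screened
#'   kinds).
#' @param kinds sensor kinds subject to the screen.
#' @return data.frame `home_id,date,sensor_inactive` covering each home's
#'   observed span.
#' @export
sensor_inactivity <- function(ev, sensors = NULL, kinds = "motion") {
  ev <- ev[ev$sensor_kind %in% kinds, , drop = FALSE]
  if (is.null(sensors)) {
    sensors <- unique(ev[, c("home_id", "sensor_id")])
  }
  out <- list()
  for (hid in unique(sensors$home_id)) {
    hev <- ev[ev$home_id == hid, , drop = FALSE]
    if (nrow(hev) == 0) next
    installed <- sensors$sensor_id[sensors$home_id == hid]
    dates <- seq(as.Date(min(hev$timestamp)), as.Date(max(hev$timestamp)), by = "day")
    evdate <- as.Date(hev$timestamp)
    flag <- vapply(dates, function(d) {
      active <- unique(hev$sensor_id[evdate == d])
      length(active) > 0 && length(setdiff(installed, active)) > 0
    }, logical(1))
    out[[hid]] <- data.frame(home_id = hid, date = dates, sensor_inactive = flag,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Flag days for exclusion
#'
#' Applies the day-exclusion rules to a day-record table:
#' \itemize{
#'   \item \strong{visitor_week / away_week}: the weekly questionnaire
#'     reported overnight visitors or residents away overnight; all 7 days
#'     covered by the report week are excluded.
#'   \item \strong{sensor_inactive}: one or more sensors inactive that day.
#'   \item \strong{post_covid}: days after the site's pandemic cutoff.
#'   \item \strong{post_move}: days after a move or resident change.
#'   \item \strong{burn_in}: the first 14 calendar days of each home's
#'     record (behaviour may differ while monitoring is novel).
#'   \item \strong{weekend}: Saturdays and Sundays — tracked separately;
#'     weekends are dropped only by the four-week daily/hourly analyses,
#'     not by the longitudinal surface.
#' }
#' `eligible` is true when no exclusion flag (visitor, away, outage, COVID,
#' move, burn-in) is set; `eligible_weekday` additionally requires a
#' Monday–Friday day.
#'
#' @param days day-record data.frame (needs `home_id`, `date`).
#' @param reports weekly-report data.frame (may be `NULL`).
#' @param metadata home metadata with `site` and optional `move_date`.
#' @param inactivity sensor-health information: either a detector table
#'   from [sensor_inactivity()] (with a `sensor_inactive` column) or a raw
#'   health/outage log with one row per silent sensor-day (`home_id`,
#'   `date`, ...), as emitted by [simulate_home()]. `NULL` disables the
#'   outage exclusion.
#' @return `days` with flag columns appended.
#' @export
flag_days <- function(days, reports = NULL, metadata, inactivity = NULL) {
  if (!is.null(inactivity) && nrow(inactivity) &&
      !"sensor_inactive" %in% names(inactivity)) {
    inactivity <- unique(inactivity[, c("home_id", "date")])
    inactivity$sensor_inactive <- TRUE
  }
  if (!all(days$home_id %in% metadata$home_id)) {
    stop("day records reference homes missing from metadata")
  }
  md <- metadata[match(days$home_id, metadata$home_id), , drop = FALSE]
  if (anyNA(md$site)) stop("missing site for one or more homes")
  n <- nrow(days)
  visitor_week <- away_week <- rep(FALSE, n)
  if (!is.null(reports) && nrow(reports)) {
    for (k in seq_len(nrow(reports))) {
      covered <- days$home_id == reports$home_id[k] &
        days$date >= reports$week_start[k] &
        days$date < reports$week_start[k] + 7
      if (isTRUE(reports$overnight_visitors[k])) visitor_week[covered] <- TRUE
      if (isTRUE(reports$away_overnight[k])) away_week[covered] <- TRUE
    }
  }
  sensor_inactive <- rep(FALSE, n)
  if (!is.null(inactivity) && nrow(inactivity)) {
    key <- paste(days$home_id, days$date)
    ikey <- paste(inactivity$home_id, inactivity$date)
    hit <- match(key, ikey)
    sensor_inactive <- ifelse(is.na(hit), FALSE, inactivity$sensor_inactive[hit])
  }
  cut <- covid_cutoffs()[md$site]
  post_covid <- days$date > as.Date(cut, origin = "1970-01-01")
  post_move <- !is.na(md$move_date) & days$date > md$move_date
  first_day <- stats::ave(as.numeric(days$date), days$home_id, FUN = min)
  burn_in <- as.numeric(days$date) - first_day < 14
  weekend <- format(days$date, "%u") %in% c("6", "7")
  days$visitor_week <- visitor_week
  days$away_week <- away_week
  days$sensor_inactive <- sensor_inactive
  days$post_covid <- post_covid
  days$post_move <- post_move
  days$burn_in <- burn_in
  days$weekend <- weekend
  days$eligible <- !(visitor_week | away_week | sensor_inactive |
                       post_covid | post_move | burn_in)
  days$eligible_weekday <- days$eligible & !weekend
  days
}

#' Select eligible days per home
#'
#' Two selection modes mirror the analysis surfaces:
#' \describe{
#'   \item{`four_week`}{the first four weeks of eligible data: up to 20
#'     eligible weekdays per home, taken in order; data-collection
#'     interruptions are ignored (gaps do not reset the count). Homes with
#'     fewer than 20 eligible weekdays (less than 4 weeks of data) are
#'     dropped.}
#'   \item{`longitudinal`}{all eligible days (weekends included); homes with
#'     180 or fewer eligible days are dropped.}
#' }
#'
#' @param flagged output of [flag_days()].
#' @param mode `"four_week"` or `"longitudinal"`.
#' @return subset of `flagged` with the selected rows; dropped homes are
#'   listed in `attr(, "dropped")`.
#' @export
eligibility_window <- function(flagged, mode = c("four_week", "longitudinal")) {
  mode <- match.arg(mode)
  keep <- list(); dropped <- character(0)
  for (hid in unique(flagged$home_id)) {
    h <- flagged[flagged$home_id == hid, , drop = FALSE]
    h <- h[order(h$date), , drop = FALSE]
    wk <- h[h$eligible_weekday, , drop = FALSE]
    if (nrow(wk) < 20) { dropped <- c(dropped, hid); next }
    if (mode == "four_week") {
      keep[[hid]] <- wk[seq_len(20), , drop = FALSE]
    } else {
      el <- h[h$eligible, , drop = FALSE]
      if (nrow(el) <= 180) { dropped <- c(dropped, hid); next }
      keep[[hid]] <- el
    }
  }
  out <- do.call(rbind, keep)
  if (is.null(out)) out <- flagged[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Remove extreme outliers from home-level summary values
#'
#' Single-pass rule: values deviating more than `sd_limit` standard
#' deviations from the mean (both computed once over all values, no
#' iteration) are removed. Zero-variance inputs remove nothing.
#'
#' @param x numeric vector of per-home summary values for one outcome.
#' @param sd_limit threshold in SD units (default 5).
#' @return list with `values` (kept), `keep` (logical index), `n_removed`.
#' @export
remove_outliers <- function(x, sd_limit = 5) {
  if (length(x) < 3) stop("outlier screen needs at least 3 values")
  s <- stats::sd(x)
  keep <- if (is.na(s) || s == 0) rep(TRUE, length(x))
          else abs(x - mean(x)) <= sd_limit * s
  list(values = x[keep], keep = keep, n_removed = sum(!keep))
}
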