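DURATION_OUTCOMES <- c("tooh", "ilsa", ROOM_OUTCOMES)

#' Home-level daily summaries
#'
#' Arithmetic mean of each outcome over the selected days (normally the
#' four-week weekday selection from [eligibility_window()]), yielding one
#' value per outcome per home.
#'
#' @param selected selected day-record rows.
#' @return data.frame, one row per home, columns `home_id` then the outcome
#'   means (hours/day, or percent for `pct_rooms_used`).
#' @export
daily_summary <- function(selected) {
  homes <- unique(selected$home_id)
  out <- data.frame(home_id = homes, stringsAsFactors = FALSE)
  for (oc in DAY_OUTCOMES) {
    out[[oc]] <- vapply(homes, function(h) {
      mean(selected[[oc]][selected$home_id == h])
    }, numeric(1))
  }
  out
}

#' Hour-to-hour (time-of-day) profiles
#'
#' Computes each duration outcome per clock hour per selected day by
#' re-running the interval metrics on 1-hour windows (hour h covers
#' \[h:00, h+1:00)), then averages per hour across days. Values are
#' reported as percent of the hour spent in the outcome, so the 24 values
#' of a profile, divided by 100 and summed, equal the home's mean daily
#' hours for that outcome (exact partition identity). The percentage of
#' rooms used is a per-day count, not a duration, and has no hourly
#' decomposition.
#'
#' @param ev event data.frame (all homes).
#' @param selected selected day-record rows (defines home-days to use).
#' @return data.frame `home_id, outcome, hour (0-23), pct`.
#' @export
hourly_summary <- function(ev, selected) {
  out <- list()
  for (hid in unique(selected$home_id)) {
    hev <- ev[ev$home_id == hid, , drop = FALSE]
    ivs <- events_to_use_intervals(hev)
    eps <- tooh_episodes(hev)
    dates <- selected$date[selected$home_id == hid]
    ## accumulate hours-in-hour sums per outcome x hour
    acc <- matrix(0, nrow = length(DURATION_OUTCOMES), ncol = 24,
                  dimnames = list(DURATION_OUTCOMES, NULL))
    for (d in as.list(dates)) {
      w0 <- day_window(d)
      for (h in 0:23) {
        w <- list(start = w0$start + h * 3600, end = w0$start + (h + 1) * 3600)
        acc["tooh", h + 1] <- acc["tooh", h + 1] + tooh(eps, w)
        acc["ilsa", h + 1] <- acc["ilsa", h + 1] + ilsa(ivs, w)
        for (loc in ROOM_OUTCOMES) {
          iv <- ivs[[loc]]
          if (!is.null(iv)) acc[loc, h + 1] <- acc[loc, h + 1] + room_use(iv, w)
        }
      }
    }
    acc <- acc / length(dates) * 100   # mean fraction of the hour, as percent
    for (oc in DURATION_OUTCOMES) {
      out[[paste(hid, oc)]] <- data.frame(
        home_id = hid, outcome = oc, hour = 0:23, pct = acc[oc, ],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape hourly profiles to a homes-by-hours matrix
#'
#' @param profiles output of [hourly_summary()].
#' @param outcome outcome name.
#' @return numeric matrix (homes x 24) with home ids as row names.
#' @export
profile_matrix <- function(profiles, outcome) {
  p <- profiles[profiles$outcome == outcome, , drop = FALSE]
  homes <- unique(p$home_id)
  m <- matrix(NA_real_, length(homes), 24, dimnames = list(homes, 0:23))
  for (h in homes) m[h, ] <- p$pct[p$home_id == h][order(p$hour[p$home_id == h])]
  m
}

#' Longitudinal slope and variability per home
#'
#' For each outcome, the ordinary least-squares slope of the daily value
#' against calendar day index (days since the home's first eligible day, so
#' gaps advance the clock) and the standard deviation of the daily values.
#' Homes need more than 180 eligible days to be meaningful and are dropped
#' otherwise.
#'
#' @param eligible eligible day-record rows (longitudinal selection).
#' @param detrended if `TRUE`, variability is the SD of the residuals about
#'   the fitted line instead of the raw daily values.
#' @return data.frame `home_id, outcome, slope` (outcome units per day),
#'   `variability` (SD), `n_days`; dropped homes in `attr(, "dropped")`.
#' @export
home_trend <- function(eligible, detrended = FALSE) {
  out <- list(); dropped <- character(0)
  for (hid in unique(eligible$home_id)) {
    h <- eligible[eligible$home_id == hid, , drop = FALSE]
    h <- h[order(h$date), , drop = FALSE]
    if (nrow(h) <= 180) { dropped <- c(dropped, hid); next }
    idx <- as.numeric(h$date - h$date[1])
    for (oc in DAY_OUTCOMES) {
      y <- h[[oc]]
      fit <- stats::lm.fit(cbind(1, idx), y)
      vb <- if (detrended) stats::sd(fit$residuals) else stats::sd(y)
      out[[paste(hid, oc)]] <- data.frame(
        home_id = hid, outcome = oc, slope = fit$coefficients[2],
        variability = vb, n_days = nrow(h), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (length(dropped)) {
    message(sprintf("home_trend: dropped %d home(s) with <= 180 eligible days",
                    length(dropped)))
  }
  attr(res, "dropped") <- dropped
  res
}

#' Slope unit conversions
#'
#' Daily metrics are carried in hours/day, so a longitudinal slope has units
#' hours/day per day. These helpers convert to the narrative units
#' seconds-per-day and minutes-per-year.
#'
#' @param slope slope in hours/day per day.
#' @param digits rounding for display; `NULL` for no rounding.
#' @return converted slope.
#' @export
slope_seconds_per_day <- function(slope, digits = 1) {
  out <- slope * 3600
  if (!is.null(digits)) out <- round(out, digits) else out
}

#' @rdname slope_seconds_per_day
#' @export
slope_minutes_per_year <- function(slope, digits = 1) {
  out <- slope * 3600 * 365 / 60
  if (!is.null(digits)) out <- round(out, digits) else out
}
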