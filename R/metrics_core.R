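## Interval algebra on half-open [start, end) intervals, seconds since epoch.
## All life-space metrics reduce to unions, intersections and clipping of
## these intervals, which is why they agree exactly with a 1-second
## occupancy-grid computation.

#' Day window for a calendar date
#'
#' @param date a `Date` (or string coercible to one).
#' @return list with `start` and `end` `POSIXct` (local midnight to next
#'   midnight on the package's fixed-offset clock; always 24 h).
#' @export
day_window <- function(date) {
  date <- as.Date(date)
  start <- as.POSIXct(paste0(format(date), "T00:00:00"),
                      format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  list(start = start, end = start + 86400)
}

## merge possibly-overlapping (or touching) intervals into disjoint sorted ones
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- as.numeric(start)[o]
  end <- as.numeric(end)[o]
  ## a new component begins where the start exceeds every earlier end
  grp <- cumsum(start > cummax(c(-Inf, end[-length(end)])))
  data.frame(start = start[!duplicated(grp)],
             end = as.numeric(tapply(end, grp, max)))
}

## total seconds of intervals intersected with [ws, we)
clip_total_seconds <- function(iv, ws, we) {
  if (nrow(iv) == 0) return(0)
  s <- pmax(as.numeric(iv$start), as.numeric(ws))
  e <- pmin(as.numeric(iv$end), as.numeric(we))
  sum(pmax(e - s, 0))
}

#' Pair motion events into room-use intervals
#'
#' Room use runs from the time of first motion detection by a sensor up to
#' the time that motion is no longer detected by that sensor. A PIR sensor
#' cannot see a stationary occupant, so these intervals are a lower bound on
#' dwell time. Each sensor's 1/0 transitions are paired into half-open
#' intervals; an unmatched trailing 1 is closed at the end of the covered
#' data span; a 0 with no preceding 1 is dropped with a warning. Intervals
#' from multiple sensors mapped to the same location are unioned.
#'
#' @param ev normalized event data.frame (motion rows are used; other rows
#'   ignored) for one home.
#' @param span_end optional override for the end of the covered span used to
#'   close a trailing active interval (defaults to the last timestamp seen).
#' @return named list, one element per location with any active interval:
#'   data.frame with numeric `start`, `end` (seconds), disjoint and sorted.
#' @export
events_to_use_intervals <- function(ev, span_end = NULL) {
  mo <- ev[ev$sensor_kind == "motion", , drop = FALSE]
  if (nrow(mo) == 0) return(list())
  if (is.null(span_end)) span_end <- max(as.numeric(ev$timestamp))
  span_end <- as.numeric(span_end)
  out <- list()
  for (loc in unique(mo$location)) {
    rows <- mo[mo$location == loc, , drop = FALSE]
    starts <- numeric(0); ends <- numeric(0)
    for (sid in unique(rows$sensor_id)) {
      sel <- rows$sensor_id == sid
      st <- rows$state[sel]
      ts <- as.numeric(rows$timestamp[sel])
      ## collapse repeated states (keep first), then states alternate
      keep <- c(TRUE, st[-1] != st[-length(st)])
      st <- st[keep]; ts <- ts[keep]
      if (length(st) && st[1] == 0L) {
        warning(sprintf("motion stop without start (sensor %s); dropped", sid))
        st <- st[-1]; ts <- ts[-1]
      }
      if (length(st) == 0) next
      s <- ts[st == 1L]
      e <- ts[st == 0L]
      if (length(e) < length(s)) e <- c(e, max(span_end, s[length(s)]))
      ok <- e > s
      starts <- c(starts, s[ok]); ends <- c(ends, e[ok])
    }
    iv <- merge_intervals(starts, ends)
    if (nrow(iv)) out[[loc]] <- iv
  }
  out
}

#' Room-use duration within a window
#'
#' @param iv disjoint interval data.frame for one location (numeric seconds).
#' @param window list with `start`, `end` (see [day_window()]).
#' @return duration in hours, clipped to the window.
#' @export
room_use <- function(iv, window) {
  clip_total_seconds(iv, window$start, window$end) / 3600
}

#' Independent life-space activity (ILSA) within a window
#'
#' ILSA is the time during which at least two distinct rooms are in
#' simultaneous use — the only condition under which at least two active
#' people are known with certainty to be in the home. Time with three or
#' more rooms simultaneously active is counted once (measure of the union),
#' not once per pair.
#'
#' @param iv_by_loc named list of disjoint interval data.frames per
#'   location, as from [events_to_use_intervals()].
#' @param window list with `start`, `end`.
#' @return duration in hours.
#' @export
ilsa <- function(iv_by_loc, window) {
  if (length(iv_by_loc) < 2) return(0)
  ws <- as.numeric(window$start); we <- as.numeric(window$end)
  pts <- numeric(0); deltas <- numeric(0)
  for (iv in iv_by_loc) {
    s <- pmax(as.numeric(iv$start), ws)
    e <- pmin(as.numeric(iv$end), we)
    ok <- e > s
    pts <- c(pts, s[ok], e[ok])
    deltas <- c(deltas, rep(1, sum(ok)), rep(-1, sum(ok)))
  }
  if (length(pts) == 0) return(0)
  o <- order(pts, -deltas)            # starts before ends at identical instants
  pts <- pts[o]; deltas <- deltas[o]
  depth <- cumsum(deltas)
  gaps <- diff(pts)
  sum(gaps[depth[-length(depth)] >= 2]) / 3600
}

#' Time-out-of-home (TOOH) episodes
#'
#' A TOOH episode runs between two door status changes — door open at
#' \eqn{t_1}, at least one close, and the next door open at \eqn{t_2} —
#' during which no motion was detected by any motion sensor. All egress-door
#' sensors of a home are pooled into a single "any egress door" channel.
#'
#' "No motion detected" is an interval condition, not an event condition: a
#' PIR can sit in the motion-detected state across the whole episode without
#' emitting a transition inside it. An episode is therefore voided when any
#' motion-detection interval overlaps the open interval \eqn{(t_1, t_2)}
#' with positive measure (or a stray unpaired motion event falls strictly
#' inside). Detection that ends exactly at the door opening — the resident
#' tripping a sensor on the way out — does not void the episode.
#'
#' @param ev normalized event data.frame for one home.
#' @param min_episode minimum episode length in seconds to count (default 0).
#' @return data.frame of episodes with numeric `start`, `end`.
#' @export
tooh_episodes <- function(ev, min_episode = 0) {
  doors <- ev[ev$sensor_kind == "door", , drop = FALSE]
  if (nrow(doors) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  o <- order(doors$timestamp)
  dts <- as.numeric(doors$timestamp)[o]
  dst <- doors$state[o]
  mts <- sort(as.numeric(ev$timestamp[ev$sensor_kind == "motion"]))
  miv <- suppressWarnings(events_to_use_intervals(ev))
  miv <- if (length(miv)) do.call(rbind, miv) else data.frame(start = numeric(0),
                                                              end = numeric(0))
  opens <- which(dst == 1L)
  starts <- numeric(0); ends <- numeric(0)
  if (length(opens) >= 2) {
    for (k in seq_len(length(opens) - 1)) {
      i <- opens[k]; j <- opens[k + 1]
      if (!any(dst[(i + 1):(j - 1)][seq_len(max(j - i - 1, 0))] == 0L)) next
      t1 <- dts[i]; t2 <- dts[j]
      if (t2 - t1 < min_episode) next
      detected <- any(pmin(miv$end, t2) > pmax(miv$start, t1)) ||
        any(mts > t1 & mts < t2)
      if (!detected) { starts <- c(starts, t1); ends <- c(ends, t2) }
    }
  }
  data.frame(start = starts, end = ends)
}

#' Time out of home within a window
#'
#' @param ev normalized event data.frame for one home, or a precomputed
#'   episode data.frame from [tooh_episodes()].
#' @param window list with `start`, `end`.
#' @param min_episode minimum episode length in seconds.
#' @return duration in hours; episodes spanning midnight contribute only
#'   their in-window part.
#' @export
tooh <- function(ev, window, min_episode = 0) {
  ep <- if (is.data.frame(ev) && identical(names(ev), c("start", "end"))) ev
        else tooh_episodes(ev, min_episode)
  clip_total_seconds(ep, window$start, window$end) / 3600
}

#' Percentage of rooms used within a window
#'
#' Number of distinct motion locations with at least one event in the
#' window, divided by the number of installed motion sensors.
#'
#' @param ev event data.frame for one home.
#' @param window list with `start`, `end`.
#' @param n_rooms installed motion-sensor count (must be >= 1).
#' @return percent in \[0, 100\].
#' @export
pct_rooms_used <- function(ev, window, n_rooms) {
  if (n_rooms < 1) stop("n_rooms must be >= 1")
  mo <- ev[ev$sensor_kind == "motion", , drop = FALSE]
  ts <- as.numeric(mo$timestamp)
  inw <- ts >= as.numeric(window$start) & ts < as.numeric(window$end)
  100 * length(unique(mo$location[inw])) / n_rooms
}

ROOM_OUTCOMES <- c("livingroom", "kitchen", "bathroom", "bedroom1")
DAY_OUTCOMES <- c("tooh", "ilsa", ROOM_OUTCOMES, "pct_rooms_used")

#' Per-day life-space metric vector for one home
#'
#' Computes TOOH, ILSA, use of the living room, kitchen, bathroom, and main
#' bedroom (`bedroom1` only; additional bedrooms still contribute to ILSA
#' and percentage of rooms used but are not reported as a room-use outcome),
#' and the percentage of rooms used, for one calendar day.
#'
#' @param ev normalized event data.frame for one home.
#' @param date calendar date.
#' @param n_rooms installed motion-sensor count.
#' @param iv_by_loc,episodes optional precomputed use intervals / TOOH
#'   episodes for the whole record (to avoid recomputation across days).
#' @return one-row data.frame: `home_id`, `date`, `tooh`, `ilsa`,
#'   `livingroom`, `kitchen`, `bathroom`, `bedroom1` (hours/day),
#'   `pct_rooms_used` (percent).
#' @export
day_metrics <- function(ev, date, n_rooms, iv_by_loc = NULL, episodes = NULL) {
  if (is.null(iv_by_loc)) iv_by_loc <- events_to_use_intervals(ev)
  if (is.null(episodes)) episodes <- tooh_episodes(ev)
  w <- day_window(date)
  rooms <- vapply(ROOM_OUTCOMES, function(loc) {
    iv <- iv_by_loc[[loc]]
    if (is.null(iv)) 0 else room_use(iv, w)
  }, numeric(1))
  data.frame(
    home_id = if (nrow(ev)) ev$home_id[1] else NA_character_,
    date = as.Date(date),
    tooh = tooh(episodes, w),
    ilsa = ilsa(iv_by_loc, w),
    livingroom = rooms[["livingroom"]],
    kitchen = rooms[["kitchen"]],
    bathroom = rooms[["bathroom"]],
    bedroom1 = rooms[["bedroom1"]],
    pct_rooms_used = pct_rooms_used(ev, w, n_rooms),
    stringsAsFactors = FALSE
  )
}

#' Day records for a whole cohort
#'
#' Applies [day_metrics()] to every home and every calendar day spanned by
#' that home's events.
#'
#' @param ev event data.frame (any number of homes).
#' @param metadata home metadata (for `n_rooms`).
#' @return data.frame of day records, one row per home-day.
#' @export
day_records <- function(ev, metadata) {
  out <- vector("list", nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    hid <- metadata$home_id[i]
    hev <- ev[ev$home_id == hid, , drop = FALSE]
    if (nrow(hev) == 0) next
    ivs <- events_to_use_intervals(hev)
    eps <- tooh_episodes(hev)
    dates <- seq(as.Date(min(hev$timestamp)), as.Date(max(hev$timestamp)), by = "day")
    rows <- lapply(dates, function(d) {
      day_metrics(hev, d, metadata$n_rooms[i], iv_by_loc = ivs, episodes = eps)
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
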