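#' @keywords internal
"_PACKAGE"

MOTION_LOCATIONS <- c("livingroom", "kitchen", "bathroom", "bedroom1",
                      "bedroom2plus", "other")
SITES <- c("OHSU", "VA", "RUSH")

#' Parse ISO-8601 naive local timestamps
#'
#' Timestamps in the event logs are naive local wall-clock times with
#' 1-second resolution (`YYYY-MM-DDTHH:MM:SS`). They are represented
#' internally as `POSIXct` on a fixed-offset clock (tz = "UTC"), so every
#' calendar day is exactly 24 h long.
#'
#' @param x character vector of timestamps.
#' @return `POSIXct` vector.
#' @export
parse_sensor_time <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out) && !anyNA(x)) {
    bad <- x[is.na(out)]
    stop("unparseable timestamp(s): ", paste(utils::head(bad, 3), collapse = ", "))
  }
  out
}

format_sensor_time <- function(x) format(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read a sensor event log
#'
#' Reads a flat state-change log with header
#' `home_id,timestamp,sensor_id,sensor_kind,location,state`. Motion sensors
#' report `state = 1` when motion is first detected and `state = 0` when
#' motion is no longer detected; door contact sensors report `1` = open,
#' `0` = closed. Motion locations come from a closed vocabulary
#' (`livingroom`, `kitchen`, `bathroom`, `bedroom1`, `bedroom2plus`,
#' `other`); door sensors carry a free-text egress-door label.
#'
#' Events are returned in stable timestamp order. Within each sensor,
#' repeated identical states (PIR retrigger chatter) are collapsed to the
#' first occurrence when `normalize = TRUE`; the number of collapsed rows is
#' recorded in `attr(, "log")`.
#'
#' @param path path to the CSV file.
#' @param normalize collapse repeated identical states per sensor.
#' @param auto_sort if `TRUE` (default), rows that are out of time order
#'   within a sensor are sorted; if `FALSE` such files are an error.
#' @return data.frame of events with columns `home_id`, `timestamp`
#'   (POSIXct), `sensor_id`, `sensor_kind`, `location`, `state`, plus a
#'   `"log"` attribute counting normalization actions.
#' @export
read_events <- function(path, normalize = TRUE, auto_sort = TRUE) {
  if (!file.exists(path)) stop("event file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("home_id", "timestamp", "sensor_id", "sensor_kind", "location", "state")
  if (!identical(names(raw), need)) {
    stop("event file header must be: ", paste(need, collapse = ","))
  }
  ev <- data.frame(
    home_id = raw$home_id,
    timestamp = if (nrow(raw)) parse_sensor_time(raw$timestamp) else parse_sensor_time(character()),
    sensor_id = raw$sensor_id,
    sensor_kind = raw$sensor_kind,
    location = raw$location,
    state = suppressWarnings(as.integer(raw$state)),
    stringsAsFactors = FALSE
  )
  validate_events(ev, auto_sort = auto_sort)
  ord <- order(ev$timestamp)                      # stable: ties keep input order
  ev <- ev[ord, , drop = FALSE]
  rownames(ev) <- NULL
  log <- list(n_rows = nrow(ev), n_collapsed = 0L)
  if (normalize) {
    keep <- normalized_keep(ev)
    log$n_collapsed <- sum(!keep)
    if (log$n_collapsed > 0) {
      warning(sprintf("collapsed %d repeated-state event(s)", log$n_collapsed))
      ev <- ev[keep, , drop = FALSE]
      rownames(ev) <- NULL
    }
  }
  attr(ev, "log") <- log
  ev
}

## index of rows to keep so states alternate 1/0 within each sensor
normalized_keep <- function(ev) {
  if (nrow(ev) == 0) return(logical(0))
  keep <- rep(TRUE, nrow(ev))
  for (sid in unique(ev$sensor_id)) {
    idx <- which(ev$sensor_id == sid)
    st <- ev$state[idx]
    dup <- c(FALSE, st[-1] == st[-length(st)])
    keep[idx[dup]] <- FALSE
  }
  keep
}

#' Normalize an event table in memory
#'
#' Same collapse rule as [read_events()]: within each sensor, consecutive
#' identical states are reduced to the first occurrence.
#' @param ev event data.frame.
#' @return normalized event data.frame.
#' @export
normalize_events <- function(ev) {
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  ev <- ev[normalized_keep(ev), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Validate a sensor event table
#'
#' Checks the structural invariants of the event log: states are 0/1,
#' motion locations come from the closed vocabulary, and timestamps are
#' non-decreasing within each sensor.
#'
#' @param ev event data.frame.
#' @param auto_sort tolerate out-of-order rows (they are sorted downstream).
#' @return `ev`, invisibly; errors describe the first violation found.
#' @export
validate_events <- function(ev, auto_sort = TRUE) {
  if (nrow(ev) == 0) return(invisible(ev))
  if (anyNA(ev$state) || !all(ev$state %in% c(0L, 1L))) {
    stop("event states must be 0 or 1")
  }
  if (!all(ev$sensor_kind %in% c("motion", "door"))) {
    stop("sensor_kind must be 'motion' or 'door'")
  }
  badloc <- setdiff(unique(ev$location[ev$sensor_kind == "motion"]), MOTION_LOCATIONS)
  if (length(badloc)) {
    stop("unknown motion location label(s): ", paste(badloc, collapse = ", "),
         " (vocabulary: ", paste(MOTION_LOCATIONS, collapse = ", "), ")")
  }
  if (!auto_sort) {
    for (sid in unique(ev$sensor_id)) {
      ts <- ev$timestamp[ev$sensor_id == sid]
      if (is.unsorted(ts)) stop("non-monotone timestamps for sensor ", sid)
    }
  }
  invisible(ev)
}

#' Write a sensor event log
#'
#' Inverse of [read_events()]; well-formed tables round-trip bit-identically
#' (LF line endings, UTF-8, ISO-8601 timestamps).
#' @param ev event data.frame.
#' @param path output path.
#' @export
write_events <- function(ev, path) {
  out <- data.frame(
    home_id = ev$home_id,
    timestamp = format_sensor_time(ev$timestamp),
    sensor_id = ev$sensor_id,
    sensor_kind = ev$sensor_kind,
    location = ev$location,
    state = ev$state,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read per-home metadata
#'
#' One row per home: resident count, MCI-home status (a home is an MCI home
#' when at least one resident was diagnosed with MCI at baseline), home-mean
#' age and education, sex and ethnicity counts, number of installed motion
#' sensors (`n_rooms`), study site, and an optional move / resident-change
#' date after which data are excluded.
#'
#' @param path metadata CSV with columns `home_id,n_residents,mci_home,
#'   mean_age,n_female,n_male,n_white,n_other_ethnicity,mean_education,
#'   n_rooms,site,move_date` (`move_date` may be empty).
#' @return data.frame keyed by `home_id`.
#' @export
read_home_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  md$mci_home <- as.logical(md$mci_home)
  if (!"move_date" %in% names(md)) md$move_date <- NA_character_
  md$move_date <- as.Date(ifelse(md$move_date == "" | is.na(md$move_date),
                                 NA_character_, md$move_date))
  validate_home_metadata(md)
  md
}

#' @rdname read_home_metadata
#' @param md metadata data.frame.
#' @export
validate_home_metadata <- function(md) {
  if (anyDuplicated(md$home_id)) stop("duplicate home_id in metadata")
  if (!all(md$n_residents %in% c(1L, 2L))) stop("n_residents must be 1 or 2")
  bad <- md$n_female + md$n_male != md$n_residents
  if (any(bad)) {
    stop("n_female + n_male != n_residents for home(s): ",
         paste(md$home_id[bad], collapse = ", "))
  }
  bad <- md$n_white + md$n_other_ethnicity != md$n_residents
  if (any(bad)) {
    stop("ethnicity counts do not sum to n_residents for home(s): ",
         paste(md$home_id[bad], collapse = ", "))
  }
  if (any(md$n_rooms < 1)) stop("n_rooms must be >= 1")
  if (!all(md$site %in% SITES)) {
    stop("site must be one of: ", paste(SITES, collapse = ", "))
  }
  invisible(md)
}

#' @rdname read_home_metadata
#' @export
write_home_metadata <- function(md, path) {
  out <- md
  out$move_date <- ifelse(is.na(out$move_date), "", as.character(out$move_date))
  out$mci_home <- ifelse(out$mci_home, "TRUE", "FALSE")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Read weekly self-report logs
#'
#' Weekly questionnaires record whether any visitors stayed overnight or the
#' residents were away from home overnight during the week starting
#' `week_start` (the report covers the 7 days from that date).
#'
#' @param path CSV with columns `home_id,week_start,overnight_visitors,
#'   away_overnight`.
#' @return data.frame with `week_start` as `Date` and logical flags.
#' @export
read_weekly_reports <- function(path) {
  wr <- utils::read.csv(path, stringsAsFactors = FALSE)
  wr$week_start <- as.Date(wr$week_start)
  wr$overnight_visitors <- as.logical(wr$overnight_visitors)
  wr$away_overnight <- as.logical(wr$away_overnight)
  if (anyNA(wr$week_start)) stop("unparseable week_start")
  key <- paste(wr$home_id, wr$week_start)
  if (anyDuplicated(key)) {
    stop("duplicate week_start for home(s): ",
         paste(unique(wr$home_id[duplicated(key)]), collapse = ", "))
  }
  wr
}

#' @rdname read_weekly_reports
#' @param wr weekly-report data.frame.
#' @export
write_weekly_reports <- function(wr, path) {
  out <- data.frame(
    home_id = wr$home_id,
    week_start = as.character(wr$week_start),
    overnight_visitors = ifelse(wr$overnight_visitors, "TRUE", "FALSE"),
    away_overnight = ifelse(wr$away_overnight, "TRUE", "FALSE"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
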