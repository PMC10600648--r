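## Shared fixtures and independent brute-force oracles.

## The worked single-day example: one door cycle plus bedroom/living-room
## motion, with the published timestamps.
figure1_events <- function(date = "2019-01-07") {
  tstr <- c("03:01:15", "03:01:20", "03:12:13", "03:13:01",
            "03:20:32", "03:25:47", "03:56:28")
  data.frame(
    home_id = "h1",
    timestamp = parse_sensor_time(paste0(date, "T", tstr)),
    sensor_id = c("d1", "d1", "d1", "m_bed", "m_liv", "m_bed", "m_liv"),
    sensor_kind = c("door", "door", "door", "motion", "motion", "motion", "motion"),
    location = c("frontdoor", "frontdoor", "frontdoor",
                 "bedroom1", "livingroom", "bedroom1", "livingroom"),
    state = c(1L, 0L, 1L, 1L, 1L, 0L, 0L),
    stringsAsFactors = FALSE
  )
}

make_events <- function(home_id, times, sensor_id, kind, location, state,
                        date = "2019-01-07") {
  data.frame(
    home_id = home_id,
    timestamp = as.POSIXct(paste0(date, "T00:00:00"),
                           format = "%Y-%m-%dT%H:%M:%S", tz = "UTC") + times,
    sensor_id = sensor_id, sensor_kind = kind, location = location,
    state = as.integer(state), stringsAsFactors = FALSE
  )
}

## random one-day event stream for one home: well-formed alternating motion
## transitions on a few locations plus door open/close cycles
random_stream <- function(seed, locations = c("livingroom", "kitchen",
                                              "bathroom", "bedroom1")) {
  set.seed(seed)
  disjoint <- function(s, e, cap = 86399) {
    o <- order(s); s <- s[o]; e <- pmin(e[o], cap)
    ks <- numeric(0); ke <- numeric(0); last <- -Inf
    for (i in seq_along(s)) {
      if (s[i] > last && e[i] > s[i]) {
        ks <- c(ks, s[i]); ke <- c(ke, e[i]); last <- e[i]
      }
    }
    cbind(ks, ke)
  }
  rows <- list()
  for (loc in sample(locations, sample(2:4, 1))) {
    n_sensor <- sample(1:2, 1)        # sometimes two sensors in one room
    for (k in seq_len(n_sensor)) {
      n_iv <- sample(1:6, 1)
      s <- sort(sample(0:86200, n_iv))
      iv <- disjoint(s, s + sample(30:4000, n_iv, replace = TRUE))
      if (nrow(iv) == 0) next
      rows[[paste(loc, k)]] <- make_events(
        "h1", as.vector(rbind(iv[, 1], iv[, 2])), paste0("m_", loc, k),
        "motion", loc,
        as.vector(rbind(rep(1, nrow(iv)), rep(0, nrow(iv)))))
    }
  }
  n_cycle <- sample(0:4, 1)
  if (n_cycle > 0) {
    op <- sort(sample(0:85000, n_cycle))
    iv <- disjoint(op, op + sample(3:600, n_cycle, replace = TRUE))
    if (nrow(iv)) {
      rows[["door"]] <- make_events(
        "h1", as.vector(rbind(iv[, 1], iv[, 2])), "d1", "door", "frontdoor",
        as.vector(rbind(rep(1, nrow(iv)), rep(0, nrow(iv)))))
    }
  }
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(make_events("h1", numeric(0), character(0),
                                      character(0), character(0), integer(0)))
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

## ---- 1-second occupancy-grid oracles -------------------------------------
## Per-second motion indicator per location over [win_start, win_start+n).
## Pairing is recomputed from scratch with run-length logic per sensor.
grid_states <- function(ev, win_start, n = 86400) {
  mo <- ev[ev$sensor_kind == "motion", , drop = FALSE]
  span_end <- if (nrow(ev)) max(as.numeric(ev$timestamp)) else win_start
  secrange <- function(a, b) if (b < a) numeric(0) else seq(a, b)
  out <- list()
  for (loc in unique(mo$location)) {
    on <- logical(n)
    rows <- mo[mo$location == loc, , drop = FALSE]
    for (sid in unique(rows$sensor_id)) {
      st <- rows$state[rows$sensor_id == sid]
      ts <- as.numeric(rows$timestamp[rows$sensor_id == sid])
      cur <- NA_real_
      for (i in seq_along(st)) {
        if (st[i] == 1L) {
          if (is.na(cur)) cur <- ts[i]
        } else if (!is.na(cur)) {
          idx <- secrange(max(cur, win_start), min(ts[i], win_start + n) - 1)
          on[idx - win_start + 1] <- TRUE
          cur <- NA_real_
        }
      }
      if (!is.na(cur) && span_end > cur) {
        idx <- secrange(max(cur, win_start), min(span_end, win_start + n) - 1)
        on[idx - win_start + 1] <- TRUE
      }
    }
    out[[loc]] <- on
  }
  out
}

oracle_room_use <- function(ev, loc, win_start, n = 86400) {
  g <- grid_states(ev, win_start, n)
  if (is.null(g[[loc]])) 0 else sum(g[[loc]]) / 3600
}

oracle_ilsa <- function(ev, win_start, n = 86400) {
  g <- grid_states(ev, win_start, n)
  if (length(g) < 2) return(0)
  depth <- Reduce(`+`, lapply(g, as.integer))
  sum(depth >= 2) / 3600
}

## enumerate open-close-open door triples; an episode counts when no
## motion-detected second overlaps its interior
oracle_tooh <- function(ev, win_start, n = 86400) {
  doors <- ev[ev$sensor_kind == "door", , drop = FALSE]
  if (nrow(doors) == 0) return(0)
  doors <- doors[order(doors$timestamp), , drop = FALSE]
  dts <- as.numeric(doors$timestamp); dst <- doors$state
  span_start <- min(as.numeric(ev$timestamp))
  g_full_n <- ceiling(max(as.numeric(ev$timestamp)) - span_start) + 1
  g <- grid_states(ev, span_start, g_full_n)
  motion_on <- if (length(g)) Reduce(`|`, g) else logical(g_full_n)
  total <- 0
  opens <- which(dst == 1L)
  for (k in seq_len(max(length(opens) - 1, 0))) {
    i <- opens[k]; j <- opens[k + 1]
    between <- dst[seq(i + 1, length.out = max(j - i - 1, 0))]
    if (!any(between == 0L)) next
    t1 <- dts[i]; t2 <- dts[j]
    secs <- seq(t1, t2 - 1) - span_start + 1
    secs <- secs[secs >= 1 & secs <= g_full_n]
    if (any(motion_on[secs])) next
    total <- total + max(min(t2, win_start + n) - max(t1, win_start), 0)
  }
  total / 3600
}

oracle_pct_rooms <- function(ev, win_start, n_rooms, n = 86400) {
  mo <- ev[ev$sensor_kind == "motion", , drop = FALSE]
  ts <- as.numeric(mo$timestamp)
  100 * length(unique(mo$location[ts >= win_start & ts < win_start + n])) / n_rooms
}

## physics-invariant violations for one simulated home over its whole span
physics_violations <- function(home, tol = 1e-9) {
  dr <- day_records(home$events, home$metadata)
  viol <- 0
  for (d in as.character(dr$date)) {
    ts <- truth_day_summary(home$truth, d)
    row <- dr[dr$date == as.Date(d), ]
    if (row$tooh > ts$all_out + tol) viol <- viol + 1
    if (row$ilsa > ts$co_occupancy + tol) viol <- viol + 1
    for (rm in c("livingroom", "kitchen", "bathroom", "bedroom1")) {
      tr <- if (rm %in% names(ts$dwell)) ts$dwell[[rm]] else 0
      if (row[[rm]] > tr + tol) viol <- viol + 1
    }
  }
  viol
}

## metadata table for model tests, with covariates that vary within arm
synthetic_metadata <- function(n_per_arm = 15, seed = 1) {
  set.seed(seed)
  arms <- rep(c("one_nomci", "one_mci", "two_nomci", "two_mci"),
              each = n_per_arm)
  n <- length(arms)
  two <- grepl("^two", arms)
  nres <- ifelse(two, 2L, 1L)
  nf <- ifelse(two, 1L, rbinom(n, 1, 0.6))
  nw <- pmin(rbinom(n, nres, 0.7), nres)
  data.frame(
    home_id = sprintf("home%03d", seq_len(n)),
    n_residents = nres,
    mci_home = grepl("mci$", arms) & !grepl("nomci$", arms),
    mean_age = round(rnorm(n, 73, 5), 1),
    n_female = nf, n_male = nres - nf,
    n_white = nw, n_other_ethnicity = nres - nw,
    mean_education = round(rnorm(n, 15, 2), 1),
    n_rooms = nres * 2 + sample(3:6, n, replace = TRUE),
    site = sample(c("OHSU", "VA", "RUSH"), n, replace = TRUE),
    move_date = as.Date(NA),
    arm = arms,
    stringsAsFactors = FALSE
  )
}
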