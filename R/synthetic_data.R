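## Agent-based simulator of household routines. Residents (and daytime
## visitors) move through rooms on a semi-Markov schedule with log-normal
## dwell times; PIR sensors fire only while someone is actually moving in a
## room (stationary occupants, e.g. asleep, are invisible), door contact
## sensors fire on every exit and entry. The simulator returns the emitted
## event stream together with the ground truth that produced it, so every
## pipeline metric can be checked against what actually happened.

SIM_ARMS <- c("one_nomci", "one_mci", "two_nomci", "two_mci")

#' Simulation scenario
#'
#' Collects every tunable of the household simulator with defaults chosen
#' to emulate the study conditions: four arms (1-/2-person homes crossed
#' with MCI status) with the cohort's arm sizes, half a year of monitoring,
#' and effect directions matching the reported contrasts (2-person homes:
#' lower TOOH, higher ILSA, more night kitchen/living-room activity; MCI
#' homes: fewer outings, fewer daytime visitors in 1-person homes, more
#' night activity and more within-home co-activity in 2-person homes).
#'
#' @param n_homes named integer vector of homes per arm
#'   (`one_nomci`, `one_mci`, `two_nomci`, `two_mci`).
#' @param days days of monitoring per home.
#' @param start_date first monitored day (a Monday well before the pandemic
#'   cutoffs, so default cohorts are unaffected by them).
#' @param wake_time,sleep_time,schedule_sd mean wake/sleep clock times
#'   (seconds after midnight) and their day-to-day SD.
#' @param dwell_meanlog,dwell_sdlog log-normal room dwell-time parameters
#'   (seconds).
#' @param room_weights room transition preferences for awake residents.
#' @param extra_other_rooms range (min, max) of additional sensored rooms
#'   per home beyond the core set; each is an extra low-traffic room whose
#'   sensor reports the `other` location, so installed sensor counts vary
#'   between homes of the same size.
#' @param extra_room_weight transition weight of each extra room.
#' @param outings_per_day,outings_per_day_2p mean outings per day for
#'   1-person homes / per resident in 2-person homes.
#' @param joint_outing_prob probability a 2-person home's second resident
#'   joins an outing.
#' @param outing_meanlog,outing_sdlog log-normal outing duration (seconds).
#' @param fixed_outing optional `c(start, duration)` in seconds: replaces
#'   the random outing process with one deterministic daily outing (joint
#'   in 2-person homes); used for controlled experiments.
#' @param nap_rate,nap_duration stationary (invisible) rest bouts per day.
#' @param visitor_rate,visitor_duration daytime-visitor process for
#'   1-person homes (visitors drive their ILSA; days remain eligible).
#' @param night_activity_rate per-night probability of a night-time
#'   kitchen/bathroom bout in 2-person homes.
#' @param mci effect multipliers applied to MCI homes: `outing_mult`,
#'   `visitor_mult` (1-person), `night_mult`, `nap_mult_2p` (2-person:
#'   less napping, hence more co-activity).
#' @param pir_timeout seconds after the last movement before a PIR emits
#'   motion-no-longer-detected.
#' @param fidget_gap,fidget_bout during sleep and naps a person is
#'   stationary (invisible to the PIR) apart from brief position shifts of
#'   `fidget_bout` seconds at intervals drawn uniformly from `fidget_gap`;
#'   awake occupants move continuously and are fully visible.
#' @param door_close_lag seconds between door open and close.
#' @param overnight_visitor_week_rate,away_week_rate weekly-report flag
#'   probabilities.
#' @param outage_rate per sensor-day probability of a silent (dead) sensor.
#' @param pet_rate optional pet noise agent: mean pet-triggered motion
#'   bouts per day (0 = off).
#' @param seed base seed; each home derives its own stream from it.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_homes = c(one_nomci = 102L, one_mci = 27L,
                                     two_nomci = 28L, two_mci = 24L),
                         days = 180L,
                         start_date = as.Date("2019-01-07"),
                         wake_time = 7 * 3600, sleep_time = 23 * 3600,
                         schedule_sd = 1800,
                         dwell_meanlog = log(1200), dwell_sdlog = 0.6,
                         room_weights = c(livingroom = 0.40, kitchen = 0.25,
                                          bathroom = 0.10, bedroom1 = 0.10,
                                          other = 0.15),
                         extra_other_rooms = c(0L, 4L),
                         extra_room_weight = 0.03,
                         outings_per_day = 1.3, outings_per_day_2p = 1.0,
                         joint_outing_prob = 0.5,
                         outing_meanlog = log(1.3 * 3600), outing_sdlog = 0.5,
                         fixed_outing = NULL,
                         nap_rate = 2, nap_duration = 3600,
                         visitor_rate = 0.35, visitor_duration = 1.5 * 3600,
                         night_activity_rate = 0.3,
                         mci = list(outing_mult = 0.8, visitor_mult = 0.4,
                                    night_mult = 2.0, nap_mult_2p = 0.5),
                         pir_timeout = 10, fidget_gap = c(300, 540),
                         fidget_bout = 6, door_close_lag = 5,
                         overnight_visitor_week_rate = 0.04,
                         away_week_rate = 0.03,
                         outage_rate = 0.01, pet_rate = 0, seed = 1L) {
  sc <- as.list(environment())
  stopifnot(all(SIM_ARMS %in% names(sc$n_homes)), sc$pir_timeout > 0,
            all(sc$room_weights >= 0), sc$days >= 1)
  if (!is.null(fixed_outing) &&
      (fixed_outing[1] < 0 || sum(fixed_outing) > 86400)) {
    stop("fixed_outing must fit inside one day")
  }
  class(sc) <- "sim_scenario"
  sc
}

## non-overlapping block sampler: keeps earlier blocks on conflict
drop_overlaps <- function(start, end) {
  if (length(start) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  keep <- rep(TRUE, length(start))
  last_end <- -Inf
  for (i in seq_along(start)) {
    if (start[i] < last_end) keep[i] <- FALSE else last_end <- end[i]
  }
  cbind(start = start[keep], end = end[keep])
}

## restless rest: a sleeping/resting person is invisible to the PIR except
## for brief position shifts at bounded intervals (gap drawn per shift)
fidget_segments <- function(loc, s, e, gap = c(300, 540), bout = 6) {
  len <- e - s
  if (len < 1) return(NULL)
  n <- ceiling(len / gap[1]) + 1
  cuts <- s + cumsum(c(0, stats::runif(n, gap[1], gap[2])))
  cuts <- c(cuts[cuts < e], e)
  ss <- cuts[-length(cuts)]; ee <- cuts[-1]
  list(loc = rep(loc, length(ss)), start = ss, end = ee,
       active = pmin(bout, ee - ss))
}

## one person's day: returns list(segments = df(loc,start,end,active),
## out = df(start,end)). Awake occupants move continuously (fully
## PIR-visible); sleep and naps are stationary apart from fidgets; every
## outing is preceded by a short awake spell (walking to the door).
sim_person_day <- function(sc, day0, room_w, mci, two_person,
                           outings = NULL, night_bout = NULL) {
  wake <- day0 + min(max(sc$wake_time + stats::rnorm(1, 0, sc$schedule_sd),
                         5 * 3600), 10 * 3600)
  bed <- day0 + min(max(sc$sleep_time + stats::rnorm(1, 0, sc$schedule_sd),
                        21 * 3600), 86400 - 600)
  segs <- list(); out <- list()
  add <- function(x) if (!is.null(x)) segs[[length(segs) + 1]] <<- x
  fidget <- function(loc, s, e) fidget_segments(loc, s, e, sc$fidget_gap,
                                                sc$fidget_bout)
  ## sleep before wake, possibly interrupted by a night bout
  sleep_pieces <- cbind(start = day0, end = wake)
  if (!is.null(night_bout)) {
    nb_s <- day0 + night_bout$start; nb_e <- min(day0 + night_bout$end, wake - 60)
    if (nb_e > nb_s) {
      add(list(loc = night_bout$loc, start = nb_s, end = nb_e,
               active = nb_e - nb_s))
      sleep_pieces <- rbind(cbind(start = day0, end = nb_s),
                            cbind(start = nb_e, end = wake))
    }
  }
  for (i in seq_len(nrow(sleep_pieces))) {
    add(fidget("bedroom1", sleep_pieces[i, 1], sleep_pieces[i, 2]))
  }
  ## blocks: outings (given) and naps, kept clear of each other and of the
  ## wake/bed boundaries so there is always an awake, visible spell between
  n_nap <- stats::rpois(1, sc$nap_rate *
                          if (two_person && mci) sc$mci$nap_mult_2p else 1)
  nap_s <- if (n_nap > 0) sort(stats::runif(n_nap, wake + 1800, bed - 5400))
           else numeric(0)
  naps <- drop_overlaps(nap_s, nap_s + sc$nap_duration)
  blocks <- data.frame(start = numeric(0), end = numeric(0), kind = character(0))
  if (!is.null(outings) && nrow(outings)) {
    blocks <- rbind(blocks, data.frame(start = outings[, 1], end = outings[, 2],
                                       kind = "out"))
  }
  if (nrow(naps)) {
    blocks <- rbind(blocks, data.frame(start = naps[, 1], end = naps[, 2],
                                       kind = "nap"))
  }
  blocks <- blocks[order(blocks$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(blocks)); last_end <- -Inf
  for (i in seq_len(nrow(blocks))) {           # earlier blocks win on conflict
    if (blocks$start[i] < last_end + 120) keep[i] <- FALSE
    else last_end <- blocks$end[i]
  }
  blocks <- blocks[keep & blocks$start >= wake + 120 & blocks$end <= bed - 60,
                   , drop = FALSE]
  ## awake filler: continuous movement between blocks
  tau <- wake; prev_loc <- "bedroom1"; bi <- 1
  while (tau < bed - 1) {
    if (bi <= nrow(blocks) && tau >= blocks$start[bi] - 1) {
      b <- blocks[bi, ]; bi <- bi + 1
      if (b$kind == "out") {
        out[[length(out) + 1]] <- data.frame(start = b$start, end = b$end)
      } else {
        loc <- sample(c("livingroom", "bedroom1"), 1)
        add(fidget(loc, tau, b$end))
        prev_loc <- loc
      }
      tau <- b$end
    } else {
      horizon <- if (bi <= nrow(blocks)) blocks$start[bi] else bed
      w <- room_w
      w[prev_loc] <- w[prev_loc] * 0.2          # discourage self-transitions
      loc <- sample(names(w), 1, prob = w / sum(w))
      dur <- min(stats::rlnorm(1, sc$dwell_meanlog, sc$dwell_sdlog),
                 horizon - tau, bed - tau)
      dur <- max(dur, 30)
      dur <- min(dur, horizon - tau, bed - tau)
      if (dur < 1) { tau <- horizon; next }
      add(list(loc = loc, start = tau, end = tau + dur, active = dur))
      prev_loc <- loc
      tau <- tau + dur
    }
  }
  ## night: settle in bed, then restless sleep
  add(fidget("bedroom1", bed, day0 + 86400))
  segments <- data.frame(
    loc = unlist(lapply(segs, `[[`, "loc")),
    start = unlist(lapply(segs, `[[`, "start")),
    end = unlist(lapply(segs, `[[`, "end")),
    active = unlist(lapply(segs, `[[`, "active")),
    stringsAsFactors = FALSE
  )
  list(segments = segments, out = do.call(rbind, out))
}

## draw a person's outing blocks for one day
sim_outings <- function(sc, day0, rate) {
  if (!is.null(sc$fixed_outing)) {
    s <- day0 + sc$fixed_outing[1]
    return(cbind(start = s, end = s + sc$fixed_outing[2]))
  }
  n <- stats::rpois(1, rate)
  if (n == 0) return(cbind(start = numeric(0), end = numeric(0)))
  lo <- day0 + 8.5 * 3600; hi <- day0 + 19 * 3600
  s <- sort(stats::runif(n, lo, hi))
  d <- pmax(pmin(stats::rlnorm(n, sc$outing_meanlog, sc$outing_sdlog),
                 3 * 3600), 600)
  ## whole-second boundaries so door events and ground truth align exactly
  drop_overlaps(floor(s), floor(pmin(s + d, day0 + 20.5 * 3600)))
}

## turn per-room active intervals into emitted PIR events, capped so that a
## sensor never reports motion outside true room occupancy
emit_motion_events <- function(home_id, segments, sc) {
  rows <- list()
  for (loc in unique(segments$loc)) {
    sg <- segments[segments$loc == loc, , drop = FALSE]
    occ <- merge_intervals(sg$start, sg$end)
    act <- sg[sg$active > 0, , drop = FALSE]
    if (nrow(act) == 0) next
    aiv <- merge_intervals(act$start, pmin(act$start + act$active, act$end))
    ## cap trailing timeout at the end of the enclosing occupancy component
    cap <- vapply(aiv$end, function(e) {
      j <- which(occ$start <= e & occ$end >= e)
      if (length(j)) occ$end[j[1]] else e
    }, numeric(1))
    emit <- merge_intervals(aiv$start, pmin(aiv$end + sc$pir_timeout, cap))
    ## first detection lands a beat after movement starts, so a bout that
    ## begins at a door-opening second does not fire exactly on the boundary
    s <- floor(emit$start) + 1; e <- floor(emit$end)
    ok <- e > s
    if (!any(ok)) next
    rows[[loc]] <- data.frame(
      home_id = home_id,
      timestamp = as.vector(rbind(s[ok], e[ok])),
      sensor_id = paste0(home_id, "_", loc),
      sensor_kind = "motion",
      location = if (grepl("^other", loc)) "other" else loc,
      state = as.vector(rbind(rep(1L, sum(ok)), rep(0L, sum(ok)))),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Simulate one home
#'
#' @param scenario a [sim_scenario()].
#' @param home_id home identifier.
#' @param arm one of `one_nomci`, `one_mci`, `two_nomci`, `two_mci`.
#' @param seed integer seed; the same seed reproduces the home bit-identically.
#' @return list with `events` (emitted sensor stream, chronological),
#'   `reports` (weekly self-reports), `truth` (per-person occupancy and
#'   out-of-home intervals, absolute seconds since the scenario epoch),
#'   `metadata` (one-row home metadata), `outages`
#'   (`date`, `sensor_id` of silent sensor-days).
#' @export
simulate_home <- function(scenario, home_id, arm = "one_nomci", seed = 1L) {
  sc <- scenario
  arm <- match.arg(arm, SIM_ARMS)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  two_person <- arm %in% c("two_nomci", "two_mci")
  mci <- arm %in% c("one_mci", "two_mci")
  n_res <- if (two_person) 2L else 1L
  rooms <- c("livingroom", "kitchen", "bathroom", "bedroom1", "other")
  if (two_person) rooms <- c(rooms, "bedroom2plus")
  n_extra <- sample(seq(sc$extra_other_rooms[1], sc$extra_other_rooms[2]), 1)
  if (n_extra > 0) rooms <- c(rooms, paste0("other", 1 + seq_len(n_extra)))
  room_w <- sc$room_weights[intersect(names(sc$room_weights), rooms)]
  if ("bedroom2plus" %in% rooms) room_w <- c(room_w, bedroom2plus = 0.05)
  extras <- setdiff(rooms, names(room_w))
  if (length(extras)) {
    room_w <- c(room_w, stats::setNames(rep(sc$extra_room_weight,
                                            length(extras)), extras))
  }
  epoch <- as.numeric(as.POSIXct(paste0(format(sc$start_date), "T00:00:00"),
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  occ <- list(); outiv <- list(); door_opens <- numeric(0)
  out_rate <- if (two_person) sc$outings_per_day_2p else sc$outings_per_day
  if (mci) out_rate <- out_rate * sc$mci$outing_mult
  vis_rate <- if (!two_person) sc$visitor_rate *
                (if (mci) sc$mci$visitor_mult else 1) else 0
  night_rate <- if (two_person) sc$night_activity_rate *
                  (if (mci) sc$mci$night_mult else 1) else 0
  for (d in seq_len(sc$days) - 1) {
    day0 <- d * 86400
    out1 <- sim_outings(sc, day0, out_rate)
    nb <- NULL
    if (night_rate > 0 && stats::runif(1) < min(night_rate, 1)) {
      nb_start <- stats::runif(1, 0.5 * 3600, 5 * 3600)
      nb <- list(start = nb_start,
                 end = nb_start + stats::runif(1, 1200, 2400),
                 loc = sample(c("kitchen", "bathroom", "livingroom"), 1,
                              prob = c(0.5, 0.3, 0.2)))
    }
    pd <- sim_person_day(sc, day0, room_w, mci, two_person, outings = out1,
                         night_bout = nb)
    pd$segments$person <- "resident1"
    occ[[length(occ) + 1]] <- pd$segments
    if (!is.null(pd$out)) {
      pd$out$person <- "resident1"
      outiv[[length(outiv) + 1]] <- pd$out
      door_opens <- c(door_opens, pd$out$start, pd$out$end)
    }
    if (two_person) {
      joint <- if (nrow(out1) && stats::runif(1) < sc$joint_outing_prob) out1
               else sim_outings(sc, day0, out_rate)
      pd2 <- sim_person_day(sc, day0, room_w, mci, two_person, outings = joint,
                            night_bout = NULL)
      pd2$segments$person <- "resident2"
      occ[[length(occ) + 1]] <- pd2$segments
      if (!is.null(pd2$out)) {
        pd2$out$person <- "resident2"
        outiv[[length(outiv) + 1]] <- pd2$out
        door_opens <- c(door_opens, pd2$out$start, pd2$out$end)
      }
    }
    ## daytime visitor (1-person homes): moves around, enters/leaves by door
    if (vis_rate > 0 && stats::runif(1) < min(vis_rate, 1)) {
      vs <- floor(day0 + stats::runif(1, 10 * 3600, 17 * 3600))
      ve <- floor(vs + stats::runif(1, 0.6, 1.4) * sc$visitor_duration)
      tau <- vs; vsegs <- list()
      while (tau < ve - 1) {
        dur <- min(stats::rlnorm(1, sc$dwell_meanlog, sc$dwell_sdlog), ve - tau)
        dur <- max(dur, 30); dur <- min(dur, ve - tau)
        loc <- sample(c("livingroom", "kitchen", "other"), 1,
                      prob = c(0.6, 0.3, 0.1))
        vsegs[[length(vsegs) + 1]] <- data.frame(
          loc = loc, start = tau, end = tau + dur, active = dur)
        tau <- tau + dur
      }
      vseg <- do.call(rbind, vsegs)
      vseg$person <- "visitor"
      occ[[length(occ) + 1]] <- vseg
      door_opens <- c(door_opens, vs, ve)
    }
    ## pet noise agent
    if (sc$pet_rate > 0) {
      n_pet <- stats::rpois(1, sc$pet_rate)
      if (n_pet > 0) {
        ps <- stats::runif(n_pet, day0, day0 + 86400 - 120)
        pseg <- data.frame(loc = sample(rooms, n_pet, replace = TRUE),
                           start = ps, end = ps + 90, active = 60,
                           person = "pet")
        occ[[length(occ) + 1]] <- pseg
      }
    }
  }
  occ <- do.call(rbind, occ)
  outiv <- if (length(outiv)) do.call(rbind, outiv)
           else data.frame(start = numeric(0), end = numeric(0),
                           person = character(0))
  ## sensor events
  ev_motion <- emit_motion_events(home_id, occ, sc)
  door_opens <- sort(unique(floor(door_opens)))
  ev_door <- if (length(door_opens)) data.frame(
    home_id = home_id,
    timestamp = as.vector(rbind(door_opens, door_opens + sc$door_close_lag)),
    sensor_id = paste0(home_id, "_door1"),
    sensor_kind = "door", location = "frontdoor",
    state = rep(c(1L, 0L), length(door_opens)),
    stringsAsFactors = FALSE
  ) else NULL
  ev <- rbind(ev_motion, ev_door)
  ev <- ev[order(ev$timestamp), , drop = FALSE]
  ## sensor outages: a silent sensor-day drops that sensor's events
  sensor_ids <- c(paste0(home_id, "_", rooms), paste0(home_id, "_door1"))
  out_mask <- matrix(stats::runif(length(sensor_ids) * sc$days) < sc$outage_rate,
                     nrow = length(sensor_ids))
  outages <- which(out_mask, arr.ind = TRUE)
  outage_df <- data.frame(
    home_id = character(0), date = as.Date(character(0)),
    sensor_id = character(0), stringsAsFactors = FALSE)
  if (nrow(outages)) {
    outage_df <- data.frame(
      home_id = home_id,
      date = sc$start_date + (outages[, 2] - 1),
      sensor_id = sensor_ids[outages[, 1]],
      stringsAsFactors = FALSE)
    evday <- ev$timestamp %/% 86400
    kill <- rep(FALSE, nrow(ev))
    for (i in seq_len(nrow(outage_df))) {
      kill <- kill | (ev$sensor_id == outage_df$sensor_id[i] &
                        evday == (outages[i, 2] - 1))
    }
    ev <- ev[!kill, , drop = FALSE]
  }
  ev$timestamp <- as.POSIXct(ev$timestamp + epoch,
                             origin = "1970-01-01", tz = "UTC")
  ev <- normalize_events(ev)
  ## weekly reports
  n_weeks <- ceiling(sc$days / 7)
  reports <- data.frame(
    home_id = home_id,
    week_start = sc$start_date + 7 * (seq_len(n_weeks) - 1),
    overnight_visitors = stats::runif(n_weeks) < sc$overnight_visitor_week_rate,
    away_overnight = stats::runif(n_weeks) < sc$away_week_rate,
    stringsAsFactors = FALSE
  )
  ## metadata
  ages <- c(one_nomci = 74, one_mci = 72, two_nomci = 70, two_mci = 74)
  if (two_person) {
    n_f <- 1L; n_m <- 1L
    n_w <- if (stats::runif(1) < 0.78) 2L else sample(0:1, 1)
  } else {
    n_f <- as.integer(stats::runif(1) < if (mci) 0.44 else 0.74)
    n_m <- 1L - n_f
    n_w <- as.integer(stats::runif(1) < if (mci) 0.8 else 0.58)
  }
  metadata <- data.frame(
    home_id = home_id, n_residents = n_res, mci_home = mci,
    mean_age = round(stats::rnorm(1, ages[arm], 5), 1),
    n_female = n_f, n_male = n_m,
    n_white = n_w, n_other_ethnicity = n_res - n_w,
    mean_education = round(stats::rnorm(1, 15, 2), 1),
    n_rooms = length(rooms),
    site = sample(SITES, 1, prob = c(69, 61, 51)),
    move_date = as.Date(NA),
    stringsAsFactors = FALSE
  )
  list(events = ev, reports = reports,
       truth = list(occupancy = occ, out = outiv, epoch = epoch,
                    start_date = sc$start_date, days = sc$days),
       metadata = metadata, outages = outage_df, arm = arm)
}

#' Simulate a full cohort
#'
#' @param scenario a [sim_scenario()].
#' @return list with pooled `events`, `metadata` (with an `arm` column),
#'   `reports`, per-home `truth`, `outages`.
#' @export
simulate_cohort <- function(scenario) {
  sc <- scenario
  homes <- list(); j <- 0
  for (arm in SIM_ARMS) {
    for (i in seq_len(sc$n_homes[[arm]])) {
      j <- j + 1
      hid <- sprintf("home%03d", j)
      homes[[hid]] <- simulate_home(sc, hid, arm,
                                    seed = (sc$seed + 7919 * j) %% 2147483647)
    }
  }
  md <- do.call(rbind, lapply(homes, `[[`, "metadata"))
  md$arm <- vapply(homes, `[[`, character(1), "arm")
  rownames(md) <- NULL
  list(
    events = do.call(rbind, lapply(homes, `[[`, "events")),
    metadata = md,
    reports = do.call(rbind, lapply(homes, `[[`, "reports")),
    truth = lapply(homes, `[[`, "truth"),
    outages = do.call(rbind, lapply(homes, `[[`, "outages"))
  )
}

#' Ground-truth day summary for one simulated home
#'
#' Computes, from the simulator's ground truth, the quantities the sensor
#' metrics can only bound from below: true per-room dwell time (any agent),
#' true all-agents-out-of-home time, and true time with at least two rooms
#' simultaneously occupied.
#'
#' @param truth `truth` element from [simulate_home()].
#' @param date calendar date.
#' @return list with `dwell` (named hours per room), `all_out` (hours),
#'   `co_occupancy` (hours).
#' @export
truth_day_summary <- function(truth, date) {
  day_idx <- as.numeric(as.Date(date) - truth$start_date)
  ws <- day_idx * 86400; we <- ws + 86400
  occ <- truth$occupancy
  dwell <- vapply(unique(occ$loc), function(loc) {
    iv <- merge_intervals(occ$start[occ$loc == loc], occ$end[occ$loc == loc])
    clip_total_seconds(iv, ws, we) / 3600
  }, numeric(1))
  ## co-occupancy: sweep over per-room occupancy unions
  iv_by_loc <- lapply(split(occ, occ$loc), function(sg)
    merge_intervals(sg$start, sg$end))
  co <- ilsa(iv_by_loc, list(start = ws, end = we))
  ## all-out: no agent has an occupancy interval covering the instant
  allocc <- merge_intervals(occ$start, occ$end)
  covered <- clip_total_seconds(allocc, ws, we)
  all_out <- (86400 - covered) / 3600
  list(dwell = dwell, all_out = all_out, co_occupancy = co)
}
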