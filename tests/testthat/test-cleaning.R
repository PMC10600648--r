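## minimal day-record table: one row per date with zero metrics
bare_days <- function(home_id, start, n) {
  dates <- as.Date(start) + seq_len(n) - 1
  data.frame(home_id = home_id, date = dates, tooh = 0, ilsa = 0,
             livingroom = 0, kitchen = 0, bathroom = 0, bedroom1 = 0,
             pct_rooms_used = 0, stringsAsFactors = FALSE)
}

bare_metadata <- function(home_id, site = "OHSU", move_date = NA) {
  data.frame(home_id = home_id, n_residents = 1, mci_home = FALSE,
             mean_age = 75, n_female = 1, n_male = 0, n_white = 1,
             n_other_ethnicity = 0, mean_education = 15, n_rooms = 5,
             site = site, move_date = as.Date(move_date),
             stringsAsFactors = FALSE)
}

test_that("a clean 100-day record is eligible exactly from day 15", {
  days <- bare_days("h1", "2019-01-01", 100)
  fl <- flag_days(days, NULL, bare_metadata("h1"))
  expect_equal(sum(fl$burn_in), 14)
  expect_identical(fl$eligible, c(rep(FALSE, 14), rep(TRUE, 86)))
  expect_true(all(fl$eligible_weekday ==
                    (fl$eligible & !format(fl$date, "%u") %in% c("6", "7"))))
})

test_that("overnight-visitor and away weeks exclude all 7 covered days", {
  days <- bare_days("h1", "2019-01-01", 50)
  wr <- data.frame(home_id = "h1",
                   week_start = as.Date(c("2019-01-21", "2019-02-04")),
                   overnight_visitors = c(TRUE, FALSE),
                   away_overnight = c(FALSE, TRUE), stringsAsFactors = FALSE)
  fl <- flag_days(days, wr, bare_metadata("h1"))
  expect_equal(sum(fl$visitor_week), 7)
  expect_equal(range(fl$date[fl$visitor_week]),
               as.Date(c("2019-01-21", "2019-01-27")))
  expect_equal(sum(fl$away_week), 7)
  expect_false(any(fl$eligible[fl$visitor_week | fl$away_week]))
})

test_that("pandemic cutoffs are site-specific", {
  days <- bare_days("r1", "2020-03-01", 30)
  days2 <- bare_days("o1", "2020-03-01", 30)
  md <- rbind(bare_metadata("r1", site = "RUSH"), bare_metadata("o1", site = "OHSU"))
  fl <- flag_days(rbind(days, days2), NULL, md)
  d21 <- fl$date == as.Date("2020-03-21")
  expect_true(fl$post_covid[d21 & fl$home_id == "r1"])
  expect_false(fl$post_covid[d21 & fl$home_id == "o1"])
  expect_false(fl$post_covid[fl$date == as.Date("2020-03-20") & fl$home_id == "r1"])
  expect_true(all(fl$post_covid[fl$date > as.Date("2020-03-23")]))
})

test_that("days after a move or resident change are excluded", {
  days <- bare_days("h1", "2019-01-01", 60)
  fl <- flag_days(days, NULL, bare_metadata("h1", move_date = "2019-02-01"))
  expect_identical(fl$post_move, fl$date > as.Date("2019-02-01"))
})

test_that("the eligible-day set on a mixed fixture matches hand enumeration", {
  ## 100 days from Tue 2019-01-01; one visitor week, one outage day,
  ## and a RUSH-style cutoff moved into range via a later start is not
  ## needed -- the fixture uses the real 2020 window instead
  days <- bare_days("h1", "2020-01-06", 100)    # Mon 2020-01-06 .. 2020-04-14
  wr <- data.frame(home_id = "h1", week_start = as.Date("2020-02-03"),
                   overnight_visitors = TRUE, away_overnight = FALSE,
                   stringsAsFactors = FALSE)
  outage <- data.frame(home_id = "h1", date = as.Date("2020-02-20"),
                       sensor_id = "h1_kitchen", stringsAsFactors = FALSE)
  fl <- flag_days(days, wr, bare_metadata("h1", site = "RUSH"), outage)
  got <- fl$date[fl$eligible]
  expected <- setdiff(
    as.Date("2020-01-06") + 14:99,                       # burn-in removed
    c(as.Date("2020-02-03") + 0:6,                       # visitor week
      as.Date("2020-02-20"),                             # outage day
      seq(as.Date("2020-03-21"), as.Date("2020-04-14"), by = "day")))  # cutoff
  expect_identical(sort(got), sort(as.Date(expected, origin = "1970-01-01")))
})

test_that("four-week selection takes the first 20 eligible weekdays only", {
  days <- bare_days("h1", "2019-01-01", 100)
  fl <- flag_days(days, NULL, bare_metadata("h1"))
  sel <- eligibility_window(fl, "four_week")
  expect_equal(nrow(sel), 20)
  expect_false(any(format(sel$date, "%u") %in% c("6", "7")))
  expect_true(all(sel$date >= as.Date("2019-01-15")))
  ## interruptions are ignored: removing a middle week shifts, not truncates
  wr <- data.frame(home_id = "h1", week_start = as.Date("2019-01-21"),
                   overnight_visitors = TRUE, away_overnight = FALSE,
                   stringsAsFactors = FALSE)
  fl2 <- flag_days(days, wr, bare_metadata("h1"))
  sel2 <- eligibility_window(fl2, "four_week")
  expect_equal(nrow(sel2), 20)
  expect_false(any(sel2$date %in% (as.Date("2019-01-21") + 0:6)))
})

test_that("homes without four weeks of data are dropped in both modes", {
  days <- bare_days("h1", "2019-01-01", 40)   # 26 post-burn-in days, 19 weekdays
  fl <- flag_days(days, NULL, bare_metadata("h1"))
  expect_equal(sum(fl$eligible_weekday), 19)
  sel <- eligibility_window(fl, "four_week")
  expect_equal(nrow(sel), 0)
  expect_equal(attr(sel, "dropped"), "h1")
})

test_that("longitudinal mode needs more than 180 eligible days", {
  days <- rbind(bare_days("short", "2019-01-01", 190),
                bare_days("long", "2019-01-01", 300))
  md <- rbind(bare_metadata("short"), bare_metadata("long"))
  fl <- flag_days(days, NULL, md)
  sel <- eligibility_window(fl, "longitudinal")
  expect_identical(unique(sel$home_id), "long")
  expect_equal(attr(sel, "dropped"), "short")
  expect_true(any(format(sel$date, "%u") %in% c("6", "7")))  # weekends retained
})

test_that("exclusion is monotone in the exclusion sources", {
  days <- bare_days("h1", "2019-01-01", 120)
  md <- bare_metadata("h1")
  base <- flag_days(days, NULL, md)
  wr <- data.frame(home_id = "h1", week_start = as.Date("2019-02-11"),
                   overnight_visitors = TRUE, away_overnight = FALSE,
                   stringsAsFactors = FALSE)
  more <- flag_days(days, wr, md)
  expect_true(all(more$eligible <= base$eligible))
  withmove <- flag_days(days, wr, bare_metadata("h1", move_date = "2019-03-01"))
  expect_true(all(withmove$eligible <= more$eligible))
})

test_that("the 5-SD outlier screen is single-pass and strict", {
  expect_equal(remove_outliers(rep(2, 10))$n_removed, 0)
  set.seed(1)
  x <- rnorm(200)
  x <- (x - mean(x)) / sd(x)          # exact unit scale
  planted <- c(x, 8)                  # > 5 SD even after inclusion
  expect_true(abs(planted[201] - mean(planted)) > 5 * sd(planted))
  scr <- remove_outliers(planted)
  expect_equal(scr$n_removed, 1)
  expect_false(scr$keep[201])
  ## values just inside the threshold are retained
  edge <- c(x, 4.9)
  expect_equal(remove_outliers(edge)$n_removed, 0)
  expect_error(remove_outliers(c(1, 2)), "at least 3")
})

test_that("the inactivity detector flags silent sensors only among active peers", {
  ev <- rbind(
    make_events("h1", c(100, 200), c("m1", "m1"), "motion", "kitchen",
                c(1, 0), date = "2019-01-07"),
    make_events("h1", c(100, 200), c("m2", "m2"), "motion", "livingroom",
                c(1, 0), date = "2019-01-07"),
    make_events("h1", c(100, 200), c("m1", "m1"), "motion", "kitchen",
                c(1, 0), date = "2019-01-08"))
  inact <- sensor_inactivity(ev)
  expect_identical(inact$sensor_inactive, c(FALSE, TRUE))
})
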