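---
title: "Methods: certainty-based life-space metrics, their cleaning rules, and the trajectory mixture model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: certainty-based life-space metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A passive-infrared (PIR) motion sensor reports a `1` when movement starts in
its field of view and a `0` when movement is no longer detected. It cannot
see a stationary person and cannot distinguish residents of a 2-person home.
The package therefore restricts itself to the three conditions that are
knowable with certainty from a home-wide stream of PIR and egress-door
events, and treats everything as interval algebra on half-open
`[start, end)` intervals at 1-second resolution:

- **Room use**: per sensor, successive `1`/`0` transitions are paired into
  detection intervals; intervals of sensors mapped to the same room are
  unioned. This is a lower bound on dwell time (a reader of the daily value
  should think "time someone was demonstrably moving in this room", not
  "time the room was occupied"). An unmatched trailing `1` is closed at the
  end of the covered data span; a `0` with no preceding `1` is dropped with
  a warning.
- **ILSA** (independent life-space activity): the measure of the set of
  instants at which at least two *distinct* rooms have active detection
  intervals. Instants with three or more active rooms are counted once
  (measure of the union); a pairwise sum would double-count them.
- **TOOH** (time out of home): for each episode delimited by a door-open at
  `t1`, at least one close, and the next open at `t2` (all egress doors
  pooled into one channel), the episode contributes `t2 - t1` if no motion
  was detected inside `(t1, t2)`. "No motion detected" is an *interval*
  condition, not an event condition: a sensor can sit in the
  motion-detected state across the entire episode without emitting a
  transition inside it, so an episode is voided whenever a detection
  interval overlaps its interior with positive measure (or a stray unpaired
  event falls strictly inside). A detection interval that ends exactly at
  `t1` — the resident tripping a hallway sensor on the way out — does not
  void the episode.
- **Percentage of rooms used**: distinct motion locations with at least one
  event in the day window, divided by the number of installed motion
  sensors.

Homes with several rooms of one type report only the main bedroom
(`bedroom1`) as a room-use outcome; additional bedrooms still contribute to
ILSA and to the percentage of rooms used, because those two metrics are
home-wide certainty conditions.

Timestamps are naive local wall-clock times held on a fixed-offset clock
(`POSIXct`, tz = "UTC"), so every day window is exactly 24 h; daylight-saving
shifts are absorbed as a one-hour level error on two days a year, which is
negligible for day-level metrics. Because every metric is a union/clip of
intervals, each equals a brute-force 1-second occupancy-grid computation
exactly, and the test suite enforces this equality on a thousand randomized
streams.

## Cleaning and eligibility

Days are excluded when: the weekly self-report flags overnight visitors or
the residents being away overnight (the report dated `week_start` covers the
7 days from that date); one or more sensors were inactive; the day falls
after the site's pandemic cutoff (2020-03-20 for the Illinois site,
2020-03-23 for the Oregon sites); the day falls after a move or a change of
residents; or the day is within the home's first 14 days of monitoring
(burn-in against observation effects).

Two readings deserved a decision:

- **Sensor inactivity.** The detector flags a day when an installed sensor
  emits zero events while a peer sensor is active — but only *motion*
  sensors are screened by default. An egress-door contact is legitimately
  silent on any day without an entry or exit, so door silence is not
  evidence of failure. When a genuine sensor-health log exists (the
  simulator emits one), `flag_days()` takes it directly and the behavioural
  detector is not needed.
- **"First 4 weeks of eligible data".** Implemented as the first up-to-20
  eligible weekdays in chronological order, with data-collection
  interruptions ignored (gaps advance the calendar, not the count). Homes
  with fewer than 20 eligible weekdays (< 4 weeks of data) are dropped from
  all analyses. Weekends are excluded only from the 4-week daily and hourly
  surfaces; the longitudinal surface uses all eligible days, because the
  day-to-day change analysis is about calendar change and a
  weekend-stripped record would distort gaps.

Home-level outlier screening removes values more than 5 SD from the mean,
with mean and SD computed once over all homes (single pass, strict
inequality). Iterating the rule would silently change exclusion counts.

## The three analysis surfaces

- **Daily summaries**: the arithmetic mean of each outcome over the selected
  weekdays — one value per outcome per home, in hours/day (percent for the
  room count).
- **Hourly profiles**: the same interval metrics recomputed on 1-hour
  windows (`[h:00, h+1:00)`), averaged per clock hour across selected days,
  reported as percent of the hour. Because clipping is additive over a
  partition of the day, the 24 values divided by 100 sum exactly to the
  daily mean in hours — a standing identity test. The percentage of rooms
  used is a per-day count, not a duration, and has no hourly decomposition.
- **Trends**: per home and outcome, the OLS slope of the daily value against
  days since the home's first eligible day, and the SD of the daily values
  (raw SD by default; detrended SD is available as an option). Homes need
  more than 180 eligible days. Internal units are hours/day, so a slope has
  units hours/day per day; `slope_seconds_per_day()` (×3600) and
  `slope_minutes_per_year()` (×3600×365/60) convert to narrative units —
  e.g. a slope of 0.0006 is 2.2 s/day at one-decimal rounding.

## Cohort comparison models

Daily summaries are compared with the home-level OLS model

```
outcome ~ two_person * mci + age + females + males + white +
          other_ethnicity + rooms + education
```

with fixed dummy coding (2-person = 1, MCI = 1). If the interaction is
significant at α = .05 (two-sided, no multiplicity correction; a
Benjamini–Hochberg flag is available for users), the analysis is stratified
by household type with the household terms removed; otherwise the
interaction is dropped and the pooled model refitted. For the percentage of
rooms used, the rooms covariate is omitted — it is the outcome's
denominator. Trend comparisons use the reduced covariate set
`two_person * mci + age` with the same stratification rule.

The stated covariate list is structurally rank-deficient: `females + males`
and `white + other_ethnicity` each equal the resident count, which is a
linear function of the intercept and the household-type dummy. One column of
each pair is therefore aliased; the fit drops it and warns, naming the
column, rather than failing — this mirrors how the same formula behaves on
any real cohort.

Latent-class membership is tested by multinomial logistic regression
(`nnet::multinom`) with the largest class as reference. Classes with ≤ 5
homes are fitted but flagged not interpretable. Quasi-separation — near
certain in small classes — is detected from exploding coefficients or
standard errors; the model is then refitted with a small ridge
(weight-decay) penalty and flagged unstable instead of silently reporting
±∞ log-odds.

## The latent-class trajectory model

Each home contributes one 24-vector of hourly values. A K-class model
assumes, for a home in class *k*,

y ~ N(X β_k, V_k),  V_k = Z G_k Zᵀ + σ²_k I,

the closed-form marginal covariance of a polynomial-growth linear mixed
model — no numerical integration is ever needed. The clock-hour covariate is
scaled to [0, 1] before polynomial expansion (a raw-hour quartic design has
condition number ≈ 10¹⁰; the scaled one is benign), and `coef()` reports
both scales (coefficient *j* divides by 23ʲ on the hour scale).

The variance families: **A** fixed effects only, one shared σ²; **B**
class-specific σ²; **C/D/E** random intercept / slope / quadratic with one
covariance shared by all classes; **F** proportional covariance
G_k = τ_k G₀ (τ₁-scale fixed by a weighted-mean-one constraint); **G**
unrestricted class-specific covariance; **H/I** model G with cubic/quartic
fixed-effect curves (the random part stays quadratic). Free parameters are
counted per family — e.g. family A with K classes and quadratic curves has
3K + (K−1) + 1 — and each count is unit-tested; BIC is −2·logL + p·log(N
homes).

Fitting is EM with conditional maximization steps: responsibilities; GLS
update of each β_k under the current V_k; a refresh of the
responsibilities; then the standard mixed-model variance updates using the
conditional moments of the random effects, pooled across classes for the
shared families. Every step is a generalized-EM step, so the observed
log-likelihood is non-decreasing across iterations — asserted on every fit
(with a 10⁻⁸ relative tolerance, because family F's proportionality update
is a coordinate ascent rather than a joint maximizer). Convergence is a
relative log-likelihood change below 10⁻⁸, capped at 500 iterations; a
class whose weight or residual variance collapses aborts the run and the
restart loop (default 20 starts, k-means++ on the raw 24-vectors, all
seeded) moves on. Labels are canonicalized by decreasing modal class size
(mixing proportion, then mean level, break ties), so results do not depend
on initial labelling.

Model selection fits the requested K × family grid, ranks **converged fits
only** by BIC, and applies the class-size rule: if the winner has a class
with fewer than 2 homes by modal assignment, the search is restricted to
smaller K and repeated. The full ranking table is returned. The search
order (full grid, rule applied to the winner) is a choice; selecting K
within each family first and then comparing families can differ in
principle, but both must pass the same class-size constraint.

## The household simulator

`simulate_home()` is an agent-based generator of the daily routine of 1- and
2-person homes: per-resident wake/sleep times (N(7:00, 30 min) and
N(23:00, 30 min)), semi-Markov room transitions with log-normal dwell times
(median 20 min) over the installed rooms, Poisson outings (1.3/day alone,
1.0/day per resident in couples, half of them joint) of log-normal duration
(median ~1.3 h, minimum 10 min), Poisson daytime visitors for 1-person homes
(0.35/day, 1.5 h), night-time kitchen/bathroom bouts for couples, optional
pet noise agents, weekly overnight-visitor/away flags, and per-sensor-day
outages. Each home also gets 0–4 extra low-traffic rooms so the
installed-sensor count varies between homes of the same size. MCI homes
modify the rates: fewer outings (×0.8), far fewer daytime visitors in
1-person homes (×0.4, which lowers their ILSA), more night activity (×2)
and less napping in couples (×0.5, which raises their daytime co-activity
and hence ILSA). These multipliers are the effect *directions* of the
study design, with magnitudes chosen once to be detectable at cohort scale;
the defaults reproduce, at the default arm sizes (102/27/28/24 homes), the
qualitative contrast table: couples show lower TOOH, higher ILSA, and more
kitchen/living-room use including at night, and the MCI effect on ILSA
reverses sign between household types.

The sensor model encodes the physics the metrics depend on: a PIR fires
only while someone is actually moving in its room; awake occupants move
continuously and are fully visible; sleeping or napping occupants are
invisible apart from brief position shifts (6 s) at intervals of 5–9
minutes; the motion-stop event trails the last movement by the PIR timeout
(default 10 s, a deployment property that real-data users must supply) but
is capped at the true end of room occupancy. Door events are emitted at the
exact entry/exit seconds, and outings begin with a short awake spell
(walking to the door). Under this model every TOOH episode during which
someone is actually home contains detectable motion, so the measured
metrics are provably bounded by their ground-truth counterparts — measured
room use ≤ true dwell, measured TOOH ≤ true all-out time, measured ILSA ≤
true multi-room co-occupancy — and the tests assert zero violations over
hundreds of simulated home-days.

What the simulator deliberately does **not** emulate: PIR retrigger chatter
and missed detections (real streams are noisier; the normalizer collapses
chatter but detection probability is 1 here), long motionless awake spells
(reading, television), sensor placement effects, person-level behavioural
heterogeneity beyond the arm multipliers, and real visit patterns. Passing
the recovery tests therefore shows the *pipeline* is correct and the effect
directions are identifiable under the stated behavioural model — not that
real cohort effect sizes would be reproduced. In real data the certainty
premise of TOOH is weaker than here: a perfectly still occupant between two
door events is indistinguishable from an empty home.

## Numerical choices and test design

- Half-open intervals everywhere; merging treats touching intervals
  (`end == next start`) as one component; boundary events never void a TOOH
  episode (strict interior test).
- Exact zero-variance inputs: the outlier screen removes nothing; OLS on a
  constant outcome returns exact zeros for all non-intercept terms.
- Problem sizes: the test suite validates oracle equivalence on 1000
  randomized one-day streams, physics bounds on 50 simulated homes × 8
  days, cohort-model recovery on 48 homes × 60 days, and trajectory
  recovery on 100 homes with a 10-residual-SD class separation — sizes
  chosen so the full suite runs in a few minutes while leaving the planted
  effects far from the decision boundaries.
- Type-I calibration of the MCI comparison is measured on a single null
  cohort (all MCI multipliers set to 1; 72 homes × 60 days) by
  re-randomizing the MCI labels within household type 200 times and
  refitting — under the null the labels are exchangeable, so each
  relabelling is an exact null replicate at a fixed simulation cost. TOOH
  is the outcome used for the calibration check: its home-level summaries
  are approximately normal. ILSA at this sample size is zero-inflated in
  1-person homes (many homes with no visitors in the window) and the
  nominal t-test size for it fluctuates by a few points — a genuine
  small-sample caveat that carries over to real analyses of skewed
  outcomes.

## Known limitations

Linear slopes are the only change-over-time model (no change points or
nonlinear trends). The trajectory mixture carries no covariates inside the
mixture — covariate effects are tested downstream on the class assignments,
which ignores assignment uncertainty. The TOOH floor for suppressing
door-ajar chatter defaults to 0 s (configurable) since no minimum episode
length is part of the definition. The DST simplification above trades two
odd-length days a year for a uniform 24-hour day grid.
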