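Package: lifespace
Title: Life-Space Activity Metrics from Passive In-Home Sensor Streams
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Turns raw event streams from per-room passive-infrared motion
    sensors and egress-door contact sensors of one- and two-person homes into
    certainty-based life-space activity metrics: time out of home (TOOH),
    independent life-space activity (ILSA, time with at least two rooms in
    simultaneous use), per-room use durations, and the percentage of rooms
    used per day. Implements day-level eligibility and exclusion rules
    (overnight-visitor and away weeks, sensor outages, pandemic cutoffs,
    residency changes, burn-in), three analysis surfaces (daily summaries,
    24-hour time-of-day profiles, longitudinal slopes and variability),
    group-comparison linear models with a stratify-on-interaction rule,
    latent-class polynomial trajectory mixtures fitted by EM with BIC model
    selection, and an agent-based household simulator that emits sensor
    streams with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    nnet,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
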