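#' Pipeline run configuration
#'
#' Collects paths, thresholds and seeds for [run_pipeline()]. Thresholds
#' default to the analysis constants used throughout the package:
#' significance level .05, 5-SD outlier screen, 14-day burn-in, more than
#' 180 days for longitudinal inclusion, and the per-site pandemic cutoffs.
#'
#' @param events,metadata,reports file paths (CSV dialects of the
#'   `read_*` functions) or already-loaded data.frames.
#' @param out_dir run directory to create.
#' @param alpha significance threshold.
#' @param outlier_sd outlier screen threshold (SD units).
#' @param longitudinal fit the longitudinal surface (slopes/variability).
#' @param lctm_outcomes outcomes to run the latent-class trajectory
#'   analysis on (`NULL` skips it).
#' @param lctm_Ks,lctm_families,lctm_restarts trajectory-model search grid.
#' @param outages optional sensor-health log (`home_id`, `date` rows for
#'   silent sensor-days); when absent, inactivity is inferred from the
#'   event stream with [sensor_inactivity()].
#' @param seed integer seed for all stochastic stages.
#' @return list of class `lifespace_config`.
#' @export
lifespace_config <- function(events, metadata, reports = NULL, out_dir,
                             alpha = 0.05, outlier_sd = 5,
                             longitudinal = TRUE,
                             lctm_outcomes = NULL, lctm_Ks = 1:3,
                             lctm_families = c("A", "B"), lctm_restarts = 5,
                             outages = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "lifespace_config"
  cfg
}

load_input <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the full analysis pipeline
#'
#' Orchestrates validate, metrics, cleaning, summaries, cohort models and
#' (optionally) the latent-class trajectory analysis as one reproducible
#' run. All intermediate tables, a results JSON, a log, and a manifest
#' (configuration, package version, seed, output checksums) are written to
#' the run directory. Every home in the metadata is accounted for: it
#' appears either among the analyzed homes or in the dropped list with a
#' reason.
#'
#' @param config a [lifespace_config()].
#' @return invisible list with the in-memory results (summaries, model
#'   fits, trends, accounting), also serialized under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  cat("", file = logf)
  stage <- "read"
  res <- tryCatch({
    ev <- load_input(cfg$events, read_events)
    md <- load_input(cfg$metadata, read_home_metadata)
    validate_home_metadata(md)
    wr <- if (!is.null(cfg$reports)) load_input(cfg$reports, read_weekly_reports)
    logline("read: %d events, %d homes, %d weekly reports",
            nrow(ev), nrow(md), if (is.null(wr)) 0L else nrow(wr))

    stage <- "metrics"
    days <- day_records(ev, md)
    utils::write.csv(days, file.path(cfg$out_dir, "daily_metrics.csv"),
                     row.names = FALSE)
    logline("metrics: %d home-days", nrow(days))

    stage <- "clean"
    inact <- if (!is.null(cfg$outages)) cfg$outages else sensor_inactivity(ev)
    flagged <- flag_days(days, wr, md, inact)
    utils::write.csv(flagged, file.path(cfg$out_dir, "flagged_days.csv"),
                     row.names = FALSE)
    sel <- eligibility_window(flagged, "four_week")
    dropped <- data.frame(home_id = attr(sel, "dropped"),
                          reason = "fewer than 4 weeks of eligible weekdays",
                          stringsAsFactors = FALSE)
    no_data <- setdiff(md$home_id, days$home_id)
    if (length(no_data)) {
      dropped <- rbind(dropped, data.frame(home_id = no_data,
                                           reason = "no sensor events"))
    }
    logline("clean: %d homes selected, %d dropped", length(unique(sel$home_id)),
            nrow(dropped))

    stage <- "summarize"
    summ <- daily_summary(sel)
    utils::write.csv(summ, file.path(cfg$out_dir, "daily_summaries.csv"),
                     row.names = FALSE)

    stage <- "models"
    fits <- lapply(stats::setNames(DAY_OUTCOMES, DAY_OUTCOMES), function(oc) {
      fit_daily_lm(summ, md, oc, alpha = cfg$alpha, outlier_sd = cfg$outlier_sd)
    })

    trends <- NULL; trend_fits <- NULL
    if (isTRUE(cfg$longitudinal)) {
      stage <- "longitudinal"
      lsel <- eligibility_window(flagged, "longitudinal")
      if (!is.null(lsel) && nrow(lsel)) {
        trends <- home_trend(lsel)
        utils::write.csv(trends, file.path(cfg$out_dir, "trends.csv"),
                         row.names = FALSE)
        trend_fits <- lapply(stats::setNames(DAY_OUTCOMES, DAY_OUTCOMES),
                             function(oc) {
          tryCatch(fit_trend_lm(trends, md, oc, "slope", alpha = cfg$alpha,
                                outlier_sd = cfg$outlier_sd),
                   error = function(e) NULL)
        })
      }
    }

    lctm_out <- NULL
    if (!is.null(cfg$lctm_outcomes)) {
      stage <- "lctm"
      profiles <- hourly_summary(ev, sel)
      utils::write.csv(profiles, file.path(cfg$out_dir, "hourly_profiles.csv"),
                       row.names = FALSE)
      lctm_out <- lapply(stats::setNames(cfg$lctm_outcomes, cfg$lctm_outcomes),
                         function(oc) {
        selm <- select_lctm(profiles, Ks = cfg$lctm_Ks,
                            families = cfg$lctm_families, outcome = oc,
                            restarts = cfg$lctm_restarts, seed = cfg$seed)
        asg <- assign_classes(selm$best)
        memb <- if (length(unique(asg$class)) >= 2) {
          tryCatch(fit_class_membership(asg, md, oc), error = function(e) NULL)
        }
        list(selection = selm, assignments = asg, membership = memb)
      })
    }

    stage <- "report"
    results <- list(
      n_homes_input = nrow(md),
      n_homes_analyzed = length(unique(sel$home_id)),
      dropped = dropped,
      daily_models = lapply(fits, function(f)
        list(outcome = f$outcome, stratified = f$stratified,
             p_interaction = f$p_interaction, tables = f$tables)),
      trend_models = if (!is.null(trend_fits))
        lapply(Filter(Negate(is.null), trend_fits), function(f)
          list(outcome = f$outcome, stratified = f$stratified,
               tables = f$tables)),
      lctm = if (!is.null(lctm_out)) lapply(lctm_out, function(l)
        list(family = l$selection$best$family, K = l$selection$best$K,
             BIC = l$selection$best$BIC,
             class_sizes = as.list(table(l$assignments$class))))
    )
    jsonlite::write_json(results, file.path(cfg$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    stopifnot(results$n_homes_analyzed + nrow(dropped) == nrow(md))
    list(selection = sel, summaries = summ, fits = fits, trends = trends,
         trend_fits = trend_fits, lctm = lctm_out, dropped = dropped,
         flagged = flagged)
  }, error = function(e) {
    logline("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  ## manifest with checksums of everything written
  outs <- list.files(cfg$out_dir, full.names = TRUE)
  outs <- outs[!basename(outs) %in% c("manifest.json", "log.txt")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("lifespace")),
    seed = cfg$seed, alpha = cfg$alpha, outlier_sd = cfg$outlier_sd,
    burn_in_days = 14, longitudinal_floor_days = 180,
    covid_cutoffs = lapply(as.list(covid_cutoffs()), as.character),
    checksums = as.list(tools::md5sum(outs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
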