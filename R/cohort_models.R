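## Group-comparison models on home-level summaries. Dummy coding is fixed:
## two_person = 1 for 2-person homes, mci = 1 for MCI homes.

covariate_frame <- function(metadata) {
  data.frame(
    home_id = metadata$home_id,
    two_person = as.integer(metadata$n_residents == 2),
    mci = as.integer(metadata$mci_home),
    age = metadata$mean_age,
    females = metadata$n_female,
    males = metadata$n_male,
    white = metadata$n_white,
    other_ethnicity = metadata$n_other_ethnicity,
    rooms = metadata$n_rooms,
    education = metadata$mean_education,
    stringsAsFactors = FALSE
  )
}

full_covariates <- c("age", "females", "males", "white", "other_ethnicity",
                     "rooms", "education")

coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             p = sm[, 4], row.names = NULL, stringsAsFactors = FALSE)
}

## lm wrapper that reports and tolerates aliased (rank-deficient) columns.
## females + males and white + other_ethnicity each sum to the resident
## count, so one column of each pair is aliased with the intercept and the
## household-type dummy; lm() returns NA for it and we surface that.
fit_ols <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    warning("aliased column(s) dropped from fit: ", paste(aliased, collapse = ", "))
  }
  fit
}

#' Compare daily summaries between household types and MCI status
#'
#' Fits the home-level linear model
#' `outcome ~ two_person * mci + age + females + males + white +
#' other_ethnicity + rooms + education` by OLS. If the household-type by
#' MCI interaction is significant at `alpha`, the analysis is stratified by
#' household type (separate fits per stratum, without the household terms);
#' otherwise the interaction is removed and the pooled model refitted. For
#' the percentage of rooms used, the rooms covariate is omitted (it already
#' defines the outcome's denominator).
#'
#' @param summaries home-level summary data.frame from [daily_summary()]
#'   (or a trend table reshaped to one column per outcome).
#' @param metadata home metadata.
#' @param outcome outcome column name.
#' @param alpha significance threshold for the interaction test (.05,
#'   two-sided, as in the primary analysis; no multiplicity correction).
#' @param outlier_sd SD threshold for the single-pass outlier screen
#'   applied to the outcome before fitting; `NULL` disables.
#' @return object of class `lifespace_lm`: list with the interaction-model
#'   table, the final fit(s), `stratified` flag, and bookkeeping.
#' @export
fit_daily_lm <- function(summaries, metadata, outcome, alpha = 0.05,
                         outlier_sd = 5) {
  cov <- covariate_frame(metadata)
  d <- merge(summaries[, c("home_id", outcome)], cov, by = "home_id")
  names(d)[2] <- "y"
  n_outliers <- 0L
  if (!is.null(outlier_sd) && nrow(d) >= 3) {
    scr <- remove_outliers(d$y, outlier_sd)
    n_outliers <- scr$n_removed
    d <- d[scr$keep, , drop = FALSE]
  }
  covs <- full_covariates
  if (outcome == "pct_rooms_used") covs <- setdiff(covs, "rooms")
  f_int <- stats::reformulate(c("two_person", "mci", "two_person:mci", covs),
                              response = "y")
  fit_int <- fit_ols(f_int, d)
  tab <- coef_table(fit_int)
  p_int <- tab$p[tab$term == "two_person:mci"]
  stratified <- length(p_int) == 1 && is.finite(p_int) && p_int < alpha
  if (stratified) {
    fits <- lapply(c(one_person = 0, two_person = 1), function(tp) {
      ds <- d[d$two_person == tp, , drop = FALSE]
      fit_ols(stats::reformulate(c("mci", covs), response = "y"), ds)
    })
  } else {
    fits <- list(pooled = fit_ols(
      stats::reformulate(c("two_person", "mci", covs), response = "y"), d))
  }
  structure(list(
    outcome = outcome, stratified = stratified, p_interaction = p_int,
    interaction_table = tab, fits = fits,
    tables = lapply(fits, coef_table),
    n_homes = nrow(d), n_outliers_removed = n_outliers, alpha = alpha
  ), class = "lifespace_lm")
}

#' @export
print.lifespace_lm <- function(x, ...) {
  cat("Home-level comparison for outcome:", x$outcome, "\n")
  cat(sprintf("n = %d homes (%d outlier(s) removed); interaction p = %s\n",
              x$n_homes, x$n_outliers_removed,
              format.pval(x$p_interaction, digits = 3)))
  if (x$stratified) {
    cat("Interaction significant: stratified by household type\n")
  } else {
    cat("Interaction not significant: pooled model without interaction\n")
  }
  for (nm in names(x$tables)) {
    cat("--", nm, "--\n")
    print(x$tables[[nm]], digits = 3)
  }
  invisible(x)
}

#' @export
coef.lifespace_lm <- function(object, ...) {
  lapply(object$fits, stats::coef)
}

#' Compare longitudinal slopes or variability between groups
#'
#' Linear model with the per-home slope (or variability) of one outcome as
#' the dependent variable and household type, MCI status, their
#' interaction, and home-mean age as covariates; the same
#' stratify-on-interaction rule as [fit_daily_lm()] applies.
#'
#' @param trends output of [home_trend()].
#' @param metadata home metadata.
#' @param outcome outcome name.
#' @param statistic `"slope"` or `"variability"`.
#' @inheritParams fit_daily_lm
#' @return `lifespace_lm` object.
#' @export
fit_trend_lm <- function(trends, metadata, outcome,
                         statistic = c("slope", "variability"),
                         alpha = 0.05, outlier_sd = 5) {
  statistic <- match.arg(statistic)
  t1 <- trends[trends$outcome == outcome, , drop = FALSE]
  summ <- data.frame(home_id = t1$home_id, y = t1[[statistic]],
                     stringsAsFactors = FALSE)
  names(summ)[2] <- outcome
  cov <- covariate_frame(metadata)
  d <- merge(summ, cov, by = "home_id")
  names(d)[2] <- "y"
  n_outliers <- 0L
  if (!is.null(outlier_sd) && nrow(d) >= 3) {
    scr <- remove_outliers(d$y, outlier_sd)
    n_outliers <- scr$n_removed
    d <- d[scr$keep, , drop = FALSE]
  }
  fit_int <- fit_ols(y ~ two_person * mci + age, d)
  tab <- coef_table(fit_int)
  p_int <- tab$p[tab$term == "two_person:mci"]
  stratified <- length(p_int) == 1 && is.finite(p_int) && p_int < alpha
  if (stratified) {
    fits <- lapply(c(one_person = 0, two_person = 1), function(tp) {
      fit_ols(y ~ mci + age, d[d$two_person == tp, , drop = FALSE])
    })
  } else {
    fits <- list(pooled = fit_ols(y ~ two_person + mci + age, d))
  }
  structure(list(
    outcome = paste(outcome, statistic, sep = "."), stratified = stratified,
    p_interaction = p_int, interaction_table = tab, fits = fits,
    tables = lapply(fits, coef_table),
    n_homes = nrow(d), n_outliers_removed = n_outliers, alpha = alpha
  ), class = "lifespace_lm")
}

#' Class-membership multinomial regression
#'
#' Tests whether household type and MCI status (with the full covariate
#' set) predict latent-class membership, by multinomial logistic
#' regression. The class with the most homes is the reference. Classes with
#' 5 or fewer homes are fitted but flagged not interpretable. Coefficients
#' with huge magnitudes or standard errors indicate (quasi-)separation; the
#' model is then refitted with a small ridge (weight-decay) penalty and
#' flagged unstable.
#'
#' @param assignments data.frame `home_id, class` (from [assign_classes()]).
#' @param metadata home metadata.
#' @param outcome label carried through to the result.
#' @param decay ridge penalty used only on separation fallback.
#' @return object of class `lifespace_multinom` with per-class coefficient
#'   tables (vs the reference class), flags, and the fitted model.
#' @export
fit_class_membership <- function(assignments, metadata, outcome = "outcome",
                                 decay = 1e-2) {
  cov <- covariate_frame(metadata)
  d <- merge(assignments, cov, by = "home_id")
  sizes <- table(d$class)
  if (length(sizes) < 2) stop("need at least 2 classes with >= 1 home")
  ref <- names(sizes)[which.max(sizes)]
  d$class <- stats::relevel(factor(d$class), ref = ref)
  form <- stats::reformulate(c("two_person", "mci", "two_person:mci",
                               full_covariates), response = "class")
  fit <- nnet::multinom(form, data = d, trace = FALSE, maxit = 500)
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(setdiff(levels(d$class), ref),
                                                     names(co)))
  se <- tryCatch(summary(fit)$standard.errors, error = function(e) co * NA)
  if (is.null(dim(se))) se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  separation <- any(!is.finite(co)) || any(abs(co) > 15, na.rm = TRUE) ||
    any(!is.finite(se)) || any(se > 50, na.rm = TRUE)
  if (separation) {
    fit <- nnet::multinom(form, data = d, trace = FALSE, maxit = 500,
                          decay = decay)
    co <- stats::coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                       dimnames = list(setdiff(levels(d$class), ref),
                                                       names(co)))
    se <- tryCatch(summary(fit)$standard.errors, error = function(e) co * NA)
    if (is.null(dim(se))) se <- matrix(se, nrow = 1, dimnames = dimnames(co))
  }
  z <- co / se
  p <- 2 * stats::pnorm(-abs(z))
  small <- names(sizes)[sizes <= 5]
  structure(list(
    outcome = outcome, reference = ref, class_sizes = sizes,
    coefficients = co, se = se, z = z, p = p,
    separation = separation,
    small_classes = small, fit = fit, n_homes = nrow(d)
  ), class = "lifespace_multinom")
}

#' @export
print.lifespace_multinom <- function(x, ...) {
  cat("Class-membership multinomial model for:", x$outcome, "\n")
  cat("Reference class (largest):", x$reference, "| class sizes:",
      paste(sprintf("%s=%d", names(x$class_sizes), x$class_sizes), collapse = ", "),
      "\n")
  if (x$separation) cat("NOTE: separation detected; ridge-penalized refit, estimates unstable\n")
  if (length(x$small_classes)) {
    cat("Classes with <= 5 homes (not interpretable):",
        paste(x$small_classes, collapse = ", "), "\n")
  }
  cat("Coefficients (log-odds vs reference):\n")
  print(round(x$coefficients, 3))
  invisible(x)
}
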