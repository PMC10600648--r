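## deterministic outcome from known coefficients on the metadata covariates
linear_outcome <- function(md, b_two = 0, b_mci = 0, b_int = 0, b_age = 0.01,
                           noise = 0, seed = 1) {
  set.seed(seed)
  two <- as.integer(md$n_residents == 2)
  mci <- as.integer(md$mci_home)
  1 + b_two * two + b_mci * mci + b_int * two * mci + b_age * md$mean_age +
    0.05 * md$n_female + 0.02 * md$n_white + 0.03 * md$n_rooms +
    0.01 * md$mean_education + rnorm(nrow(md), 0, noise)
}

as_summary <- function(md, y, outcome = "ilsa") {
  out <- data.frame(home_id = md$home_id, stringsAsFactors = FALSE)
  out[[outcome]] <- y
  out
}

test_that("noise-free coefficients are recovered to machine precision", {
  md <- synthetic_metadata(20, seed = 3)
  y <- linear_outcome(md, b_two = 0.7, b_mci = -0.4)
  fit <- suppressWarnings(fit_daily_lm(as_summary(md, y), md, "ilsa"))
  expect_false(fit$stratified)
  tb <- fit$tables$pooled
  expect_equal(tb$estimate[tb$term == "two_person"], 0.7, tolerance = 1e-8)
  expect_equal(tb$estimate[tb$term == "mci"], -0.4, tolerance = 1e-8)
  expect_equal(tb$estimate[tb$term == "age"], 0.01, tolerance = 1e-8)
})

test_that("the OLS fit equals a hand-rolled normal-equations solve", {
  md <- synthetic_metadata(15, seed = 4)
  y <- linear_outcome(md, b_two = 0.3, noise = 0.4, seed = 11)
  fit <- suppressWarnings(fit_daily_lm(as_summary(md, y), md, "ilsa"))
  tb <- fit$tables$pooled
  X <- cbind(1, as.integer(md$n_residents == 2), as.integer(md$mci_home),
             md$mean_age, md$n_female, md$n_white, md$n_rooms,
             md$mean_education)
  beta <- solve(crossprod(X), crossprod(X, y))
  terms <- c("(Intercept)", "two_person", "mci", "age", "females", "white",
             "rooms", "education")
  for (i in seq_along(terms)) {
    expect_equal(tb$estimate[tb$term == terms[i]], beta[i],
                 tolerance = 1e-8, info = terms[i])
  }
})

test_that("a planted opposite-sign interaction triggers stratification", {
  md <- synthetic_metadata(25, seed = 5)
  y <- linear_outcome(md, b_two = 1, b_mci = -0.5, b_int = 1.2,
                      noise = 0.3, seed = 6)
  fit <- suppressWarnings(fit_daily_lm(as_summary(md, y), md, "ilsa"))
  expect_true(fit$stratified)
  expect_named(fit$tables, c("one_person", "two_person"))
  t1 <- fit$tables$one_person; t2 <- fit$tables$two_person
  expect_lt(t1$estimate[t1$term == "mci"], 0)     # -0.5 in 1-person homes
  expect_gt(t2$estimate[t2$term == "mci"], 0)     # -0.5 + 1.2 in 2-person homes
})

test_that("the rooms covariate is omitted for percentage of rooms used", {
  md <- synthetic_metadata(15, seed = 7)
  y <- linear_outcome(md, noise = 0.2, seed = 8)
  f1 <- suppressWarnings(fit_daily_lm(as_summary(md, y, "pct_rooms_used"),
                                      md, "pct_rooms_used"))
  expect_false("rooms" %in% f1$interaction_table$term)
  f2 <- suppressWarnings(fit_daily_lm(as_summary(md, y), md, "ilsa"))
  expect_true("rooms" %in% f2$interaction_table$term)
})

test_that("the 5-SD screen is applied before fitting", {
  md <- synthetic_metadata(25, seed = 9)
  y <- linear_outcome(md, noise = 0.1, seed = 10)
  y[1] <- y[1] + 50
  fit <- suppressWarnings(fit_daily_lm(as_summary(md, y), md, "ilsa"))
  expect_equal(fit$n_outliers_removed, 1L)
  expect_equal(fit$n_homes, nrow(md) - 1)
})

test_that("trend comparisons use the reduced covariate set and exact zeros", {
  md <- synthetic_metadata(10, seed = 12)
  tr <- data.frame(home_id = md$home_id, outcome = "ilsa",
                   slope = 0.002, variability = 0.5, n_days = 200,
                   stringsAsFactors = FALSE)
  ## a constant outcome makes summary.lm warn about the perfect fit
  fit <- suppressWarnings(fit_trend_lm(tr, md, "ilsa", "slope",
                                       outlier_sd = NULL))
  tb <- fit$tables$pooled
  expect_true(all(tb$term %in% c("(Intercept)", "two_person", "mci", "age")))
  for (tm in c("two_person", "mci", "age")) {
    expect_equal(tb$estimate[tb$term == tm], 0, tolerance = 1e-12, info = tm)
  }
  expect_equal(tb$estimate[tb$term == "(Intercept)"], 0.002, tolerance = 1e-12)
})

test_that("class membership regression uses the largest class as reference", {
  md <- synthetic_metadata(25, seed = 13)
  set.seed(14)
  asg <- data.frame(home_id = md$home_id,
                    class = sample(1:2, nrow(md), TRUE, prob = c(0.3, 0.7)),
                    stringsAsFactors = FALSE)
  fit <- fit_class_membership(asg, md, "ilsa")
  expect_equal(fit$reference, "2")
  ## memberships independent of covariates: no strong effects
  expect_true(all(abs(fit$z[, "two_person"]) < 3, na.rm = TRUE))
  expect_true(all(abs(fit$z[, "mci"]) < 3, na.rm = TRUE))
})

test_that("small classes are flagged and separation is detected", {
  md <- synthetic_metadata(15, seed = 15)
  set.seed(16)
  asg <- data.frame(home_id = md$home_id,
                    class = c(rep(1, 57), rep(2, 3)), stringsAsFactors = FALSE)
  fit <- fit_class_membership(asg, md, "ilsa")
  expect_true("2" %in% fit$small_classes)
  ## class fully determined by household type => separation
  asg2 <- data.frame(home_id = md$home_id,
                     class = ifelse(md$n_residents == 2, 2, 1),
                     stringsAsFactors = FALSE)
  fit2 <- fit_class_membership(asg2, md, "ilsa")
  expect_true(fit2$separation)
})

test_that("a planted membership effect is recovered within 2 SE", {
  md <- synthetic_metadata(60, seed = 17)   # 240 homes
  set.seed(18)
  two <- as.integer(md$n_residents == 2)
  p2 <- plogis(-1 + 2 * two)                # log-OR 2 for 2-person homes
  asg <- data.frame(home_id = md$home_id,
                    class = 1L + rbinom(nrow(md), 1, p2),
                    stringsAsFactors = FALSE)
  fit <- fit_class_membership(asg, md, "ilsa")
  est <- fit$coefficients[, "two_person"]
  se <- fit$se[, "two_person"]
  expect_lt(abs(est - 2), 2 * se)
})
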