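## simulate profiles from a mixture of quadratic curves, optionally with
## random effects, for recovery and monotonicity checks
sim_profiles <- function(n_per_class, betas, sigma = 1, G = NULL, seed = 1) {
  set.seed(seed)
  tt <- (0:23) / 23
  X <- cbind(1, tt, tt^2)
  cls <- rep(seq_along(n_per_class), n_per_class)
  y <- t(vapply(cls, function(k) {
    mu <- as.vector(X %*% betas[[k]])
    if (!is.null(G)) {
      b <- as.vector(t(chol(G)) %*% rnorm(ncol(G)))
      mu <- mu + as.vector(X[, seq_along(b), drop = FALSE] %*% b)
    }
    mu + rnorm(24, 0, sigma)
  }, numeric(24)))
  rownames(y) <- sprintf("home%03d", seq_len(nrow(y)))
  attr(y, "class_truth") <- cls
  y
}

monotone <- function(fit) {
  tr <- fit$trace
  all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1e-3))
}

test_that("free-parameter counts are audited per family", {
  ## order-2 families: (order+1)K betas + (K-1) mixing + variance params
  expect_equal(lifespace:::lctm_n_params("A", 2), 3 * 2 + 1 + 1)
  expect_equal(lifespace:::lctm_n_params("B", 2), 6 + 1 + 2)
  expect_equal(lifespace:::lctm_n_params("C", 2), 6 + 1 + 1 + 1)
  expect_equal(lifespace:::lctm_n_params("D", 2), 6 + 1 + 1 + 3)
  expect_equal(lifespace:::lctm_n_params("E", 2), 6 + 1 + 1 + 6)
  expect_equal(lifespace:::lctm_n_params("F", 2), 6 + 1 + 2 + 6 + 1)
  expect_equal(lifespace:::lctm_n_params("G", 2), 6 + 1 + 2 + 12)
  expect_equal(lifespace:::lctm_n_params("H", 2), 8 + 1 + 2 + 12)
  expect_equal(lifespace:::lctm_n_params("I", 2), 10 + 1 + 2 + 12)
  ## BIC uses the audited count with N = number of homes
  y <- sim_profiles(c(10, 10), list(c(0, 0, 0), c(5, 0, 0)), seed = 2)
  f <- lctm(y, K = 2, family = "A", restarts = 3, seed = 1)
  expect_equal(f$BIC, -2 * f$logLik + 8 * log(20))
})

test_that("a one-class fixed-effect model reduces to polynomial OLS", {
  y <- sim_profiles(30, list(c(1, 2, -1.5)), sigma = 0.5, seed = 3)
  f <- lctm(y, K = 1, family = "A", restarts = 2, seed = 1)
  tt <- (0:23) / 23
  ols <- unname(coef(lm(colMeans(y) ~ tt + I(tt^2))))
  expect_equal(unname(as.vector(f$beta)), ols, tolerance = 1e-8)
  expect_true(f$converged)
  ## hour-scale coefficients are the scaled ones divided by 23^j
  ch <- coef(f, scale = "hours")
  expect_equal(unname(ch[2, 1]), unname(f$beta[2, 1]) / 23)
  expect_equal(unname(ch[3, 1]), unname(f$beta[3, 1]) / 23^2)
})

test_that("well-separated classes are recovered with monotone EM", {
  ## separation 10 residual SDs between the flat-low and peaked curves
  y <- sim_profiles(c(50, 50), list(c(1, 0, 0), c(1, 40, -40)),
                    sigma = 1, seed = 4)
  f <- lctm(y, K = 2, family = "A", restarts = 5, seed = 7)
  expect_true(f$converged)
  expect_true(monotone(f))
  truth <- attr(y, "class_truth")
  tab <- table(truth, f$modal)
  acc <- max(sum(diag(tab)), sum(tab[1, 2] + tab[2, 1])) / length(truth)
  expect_gte(acc, 0.99)
  ## fixed-effect curves recovered within 3 SE of pointwise curve error
  tt <- (0:23) / 23; X <- cbind(1, tt, tt^2)
  fitted_curves <- X %*% f$beta
  true_curves <- X %*% cbind(c(1, 0, 0), c(1, 40, -40))
  se_curve <- 1 / sqrt(50)    # sigma / sqrt(n_k) per time point
  for (k in 1:2) {
    dev <- min(max(abs(fitted_curves[, k] - true_curves[, 1])),
               max(abs(fitted_curves[, k] - true_curves[, 2])))
    expect_lt(dev, 3 * se_curve)
  }
})

test_that("random-effect families fit with monotone likelihood and sane variances", {
  G <- diag(c(2, 1, 0.5))
  y <- sim_profiles(c(40, 40), list(c(0, 0, 0), c(8, 4, -4)),
                    sigma = 0.7, G = G, seed = 5)
  for (fam in c("C", "E", "F", "G", "H")) {
    f <- lctm(y, K = 2, family = fam, restarts = 3, seed = 11)
    expect_true(monotone(f), info = fam)
    expect_true(all(f$sigma2 > 0), info = fam)
    if (!is.null(f$G)) {
      expect_true(all(vapply(f$G, function(g) all(eigen(g)$values > -1e-8),
                             logical(1))), info = fam)
    }
  }
  ## shared-variance families really do share their parameters
  fE <- lctm(y, K = 2, family = "E", restarts = 3, seed = 11)
  expect_equal(fE$sigma2[1], fE$sigma2[2])
  expect_equal(fE$G[[1]], fE$G[[2]])
})

test_that("posteriors are proper and labels are canonical", {
  y <- sim_profiles(c(60, 20), list(c(0, 0, 0), c(10, 0, 0)), seed = 6)
  f <- lctm(y, K = 2, family = "A", restarts = 4, seed = 3)
  expect_equal(rowSums(f$posterior), rep(1, 80), tolerance = 1e-10)
  expect_equal(sum(f$pi), 1, tolerance = 1e-10)
  ## class 1 is the largest by construction of the canonical ordering
  expect_gte(sum(f$modal == 1), sum(f$modal == 2))
  ## the same data under another seed yields the same labelled assignment
  f2 <- lctm(y, K = 2, family = "A", restarts = 4, seed = 91)
  expect_equal(f$modal, f2$modal)
})

test_that("modal assignment flags small classes", {
  y <- sim_profiles(c(30, 5), list(c(0, 0, 0), c(12, 0, 0)), seed = 8)
  f <- lctm(y, K = 2, family = "A", restarts = 4, seed = 2)
  asg <- assign_classes(f)
  expect_equal(nrow(asg), 35)
  expect_true(all(asg$posterior >= 0.5))
  sizes <- table(asg$class)
  expect_true(all(asg$small_class[asg$class == names(sizes)[sizes <= 5]]))
  f_bad <- f; f_bad$converged <- FALSE
  expect_error(assign_classes(f_bad), "converge")
})

test_that("the selection rule ranks converged fits by BIC with class collapse", {
  rk <- data.frame(family = c("I", "H", "A"), K = c(5, 5, 5),
                   logLik = c(-40, -50, -60), BIC = c(100.0, 101.0, 105.0),
                   converged = c(FALSE, TRUE, TRUE), min_class_n = c(3, 3, 3))
  ## the lowest-BIC fit did not converge, so the runner-up is chosen
  expect_equal(lifespace:::lctm_rank_select(rk), 2L)
  ## a winning fit with a < 2-home class forces a lower class count
  rk2 <- data.frame(family = "A", K = c(3, 2, 1),
                    logLik = NA, BIC = c(90, 95, 120),
                    converged = TRUE, min_class_n = c(1, 2, 40))
  expect_equal(lifespace:::lctm_rank_select(rk2), 2L)
  rk3 <- rk2; rk3$converged <- FALSE
  expect_error(lifespace:::lctm_rank_select(rk3), "converged")
})

test_that("grid search picks one class for pure noise", {
  y <- sim_profiles(40, list(c(2, 1, -1)), sigma = 1, seed = 9)
  sel <- select_lctm(y, Ks = 1:3, families = c("A", "B"),
                     restarts = 3, seed = 5)
  expect_equal(sel$best$K, 1)
})

test_that("a tiny planted class collapses the class count", {
  y <- sim_profiles(c(40, 40, 1), list(c(0, 0, 0), c(12, 0, 0), c(0, 60, -60)),
                    sigma = 1, seed = 10)
  sel <- select_lctm(y, Ks = 1:4, families = "A", restarts = 4, seed = 6)
  expect_gte(min(tabulate(sel$best$modal, sel$best$K)), 2)
  ## some richer fit isolated the singleton and was rejected for it
  rk <- sel$ranking
  expect_true(any(rk$min_class_n < 2 & rk$converged &
                    rk$BIC < sel$best$BIC, na.rm = TRUE))
})

test_that("simulated draws from a fit resemble the training profiles", {
  y <- sim_profiles(c(40, 40), list(c(0, 0, 0), c(10, 5, -5)), seed = 12)
  f <- lctm(y, K = 2, family = "B", restarts = 3, seed = 4)
  ynew <- simulate(f, seed = 13)
  expect_equal(dim(ynew), dim(y))
  expect_lt(abs(mean(ynew) - mean(y)), 1)
  pr <- predict(f, hours = 0:23)
  expect_equal(dim(pr), c(24L, 2L))
})
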