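## Latent-class trajectory mixtures for 24-point time-of-day profiles.
##
## Each home contributes one vector of 24 hourly values. A K-class model
## assumes y_i | class k ~ N(X beta_k, V_k) with V_k = Z G_k Z' + sigma_k^2 I
## the closed-form marginal covariance of a linear Gaussian mixed model, so
## no numerical integration is needed. The variance-structure families:
##   A fixed effects only, homoscedastic          (G = 0, shared sigma)
##   B fixed effects only, heteroscedastic        (G = 0, class sigma)
##   C random intercept, common structure         (q = 1, shared G, sigma)
##   D random slope, common structure             (q = 2, shared G, sigma)
##   E random quadratic, common structure         (q = 3, shared G, sigma)
##   F random quadratic, proportional:  G_k = tau_k G0, class sigma
##   G random quadratic, unrestricted class-specific G_k and sigma_k
##   H model G with cubic fixed-effect curves
##   I model G with quartic fixed-effect curves
## Fixed-effect curves are polynomials of order 2 (A-G), 3 (H) or 4 (I) in
## clock hour scaled to [0, 1] (quartic designs on raw hours are badly
## conditioned; coefficients are reported on both scales).

lctm_family_info <- function(family) {
  family <- match.arg(family, LETTERS[1:9])
  order <- switch(family, H = 3L, I = 4L, 2L)
  q <- switch(family, A = 0L, B = 0L, C = 1L, D = 2L, 3L)
  shared_G <- family %in% c("C", "D", "E")
  proportional <- family == "F"
  shared_sigma <- family %in% c("A", "C", "D", "E")
  list(family = family, order = order, q = q, shared_G = shared_G,
       proportional = proportional, shared_sigma = shared_sigma)
}

lctm_n_params <- function(family, K) {
  fi <- lctm_family_info(family)
  p <- (fi$order + 1L) * K + (K - 1L)
  p <- p + if (fi$shared_sigma) 1L else K
  if (fi$q > 0) {
    gsz <- fi$q * (fi$q + 1L) / 2L
    p <- p + if (fi$shared_G) gsz
             else if (fi$proportional) gsz + (K - 1L)
             else gsz * K
  }
  as.integer(p)
}

## k-means++ centre picking followed by one k-means pass; returns cluster ids
kmeanspp_assign <- function(y, K) {
  N <- nrow(y)
  if (K == 1) return(rep(1L, N))
  centers <- matrix(NA_real_, K, ncol(y))
  centers[1, ] <- y[sample.int(N, 1), ]
  d2 <- rowSums((y - matrix(centers[1, ], N, ncol(y), byrow = TRUE))^2)
  for (k in 2:K) {
    prob <- d2 / sum(d2)
    if (!all(is.finite(prob)) || sum(prob) == 0) prob <- rep(1 / N, N)
    centers[k, ] <- y[sample.int(N, 1, prob = prob), ]
    dk <- rowSums((y - matrix(centers[k, ], N, ncol(y), byrow = TRUE))^2)
    d2 <- pmin(d2, dk)
  }
  km <- tryCatch(stats::kmeans(y, centers = centers, iter.max = 25),
                 error = function(e) NULL)
  if (is.null(km)) max.col(-as.matrix(stats::dist(rbind(centers, y)))[-(1:K), 1:K])
  else km$cluster
}

symmetrize_psd <- function(G, floor = 1e-10) {
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  v <- pmax(e$values, floor)
  e$vectors %*% (v * t(e$vectors))
}

## one EM run from a given hard assignment; returns params or NULL if degenerate
lctm_em <- function(y, X, Z, fi, K, assign0, max_iter, tol) {
  N <- nrow(y); n <- ncol(y)
  yt <- t(y)                                    # n x N
  ## --- init from hard assignment
  beta <- matrix(0, ncol(X), K)
  sig2 <- numeric(K)
  for (k in 1:K) {
    idx <- which(assign0 == k)
    if (length(idx) == 0) idx <- sample.int(N, max(2, N %/% (2 * K)))
    yk <- colMeans(y[idx, , drop = FALSE])
    beta[, k] <- stats::lm.fit(X, yk)$coefficients
    rs <- yt[, idx, drop = FALSE] - as.vector(X %*% beta[, k])
    sig2[k] <- max(mean(rs^2), 1e-6)
  }
  if (fi$shared_sigma) sig2[] <- mean(sig2)
  G <- replicate(K, if (fi$q > 0) diag(0.05 * mean(sig2), fi$q) else
                    matrix(0, 0, 0), simplify = FALSE)
  tau <- rep(1, K)
  pi_k <- pmax(tabulate(assign0, K), 0.5) / sum(pmax(tabulate(assign0, K), 0.5))

  class_chol <- function(k) {
    V <- diag(sig2[k], n)
    if (fi$q > 0) V <- V + Z %*% G[[k]] %*% t(Z)
    chol(V)
  }
  estep <- function() {
    ll <- matrix(0, N, K)
    for (k in 1:K) {
      R <- class_chol(k)
      resid <- yt - as.vector(X %*% beta[, k])
      M <- backsolve(R, resid, transpose = TRUE)
      ll[, k] <- log(pi_k[k]) - 0.5 * (n * log(2 * pi) +
                 2 * sum(log(diag(R))) + colSums(M^2))
    }
    mx <- apply(ll, 1, max)
    w <- exp(ll - mx)
    s <- rowSums(w)
    list(r = w / s, logL = sum(mx + log(s)))
  }

  trace <- numeric(0)
  logL_prev <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    es <- estep()
    trace <- c(trace, es$logL)
    if (!is.finite(es$logL)) return(NULL)
    if (it > 1 && abs(es$logL - logL_prev) <
        tol * (abs(logL_prev) + 1e-3)) { converged <- TRUE; break }
    logL_prev <- es$logL
    r <- es$r
    Rk <- colSums(r)
    if (any(Rk < 1e-6)) return(NULL)
    pi_k <- Rk / N
    ## conditional maximization: beta by GLS under current V_k
    for (k in 1:K) {
      R <- class_chol(k)
      Vi <- chol2inv(R)
      ybar <- as.vector(yt %*% r[, k]) / Rk[k]
      XtW <- crossprod(X, Vi)
      beta[, k] <- solve(XtW %*% X, XtW %*% ybar)
    }
    ## refresh responsibilities under the new means, then update variances
    es2 <- estep()
    r <- es2$r
    Rk <- colSums(r)
    if (any(Rk < 1e-6)) return(NULL)
    Mk <- vector("list", K); Ek <- numeric(K)
    for (k in 1:K) {
      resid <- yt - as.vector(X %*% beta[, k])
      if (fi$q > 0) {
        R <- class_chol(k)
        Vi <- chol2inv(R)
        A <- G[[k]] %*% crossprod(Z, Vi)            # q x n
        bhat <- A %*% resid                         # q x N
        Sb <- G[[k]] - A %*% Z %*% G[[k]]
        Mk[[k]] <- (bhat * rep(r[, k], each = fi$q)) %*% t(bhat) / Rk[k] + Sb
        ehat <- resid - Z %*% bhat
        Ek[k] <- sum(r[, k] * colSums(ehat^2)) / Rk[k] +
          sig2[k] * (n - sig2[k] * sum(diag(Vi)))
      } else {
        Ek[k] <- sum(r[, k] * colSums(resid^2)) / Rk[k]
      }
    }
    if (fi$shared_sigma) {
      sig2[] <- sum(Rk * Ek) / (N * n)
    } else {
      sig2 <- Ek / n
    }
    if (any(sig2 < 1e-10)) return(NULL)
    if (fi$q > 0) {
      if (fi$shared_G) {
        G0 <- Reduce(`+`, Map(function(M, w) w * M, Mk, Rk)) / N
        G <- replicate(K, symmetrize_psd(G0), simplify = FALSE)
      } else if (fi$proportional) {
        G0 <- Reduce(`+`, Map(function(M, w, tk) w * M / tk, Mk, Rk, tau)) / N
        G0 <- symmetrize_psd(G0)
        G0i <- solve(G0)
        tau <- vapply(Mk, function(M) sum(diag(G0i %*% M)) / fi$q, numeric(1))
        tau <- pmax(tau, 1e-8)
        sc <- sum(Rk * tau) / N                      # identifiability scale
        tau <- tau / sc; G0 <- G0 * sc
        G <- lapply(tau, function(tk) tk * G0)
      } else {
        G <- lapply(Mk, symmetrize_psd)
      }
    }
  }
  es <- estep()
  if (length(trace) == 0 || es$logL >= trace[length(trace)] - 1e-6) {
    trace <- c(trace, es$logL)
  }
  list(beta = beta, G = G, sigma2 = sig2, tau = tau, pi = pi_k,
       r = es$r, logLik = es$logL, trace = trace,
       converged = converged, n_iter = length(trace))
}

#' Fit a latent-class trajectory model to time-of-day profiles
#'
#' Fits a K-class mixture of polynomial growth curves to per-home 24-hour
#' profiles by EM on the closed-form marginal Gaussian likelihood of the
#' underlying linear mixed model. Multiple restarts are seeded by
#' k-means++ on the raw profiles; the log-likelihood is non-decreasing over
#' EM iterations on every run.
#'
#' @param y numeric matrix, homes x 24 hourly values (percent/hour), with
#'   home ids as row names, or the long data.frame from [hourly_summary()]
#'   together with `outcome`.
#' @param K number of latent classes (>= 1).
#' @param family variance-structure family, `"A"`-`"I"` (see Details in the
#'   package vignette).
#' @param outcome outcome name when `y` is a long profile data.frame.
#' @param restarts number of EM restarts (default 20).
#' @param seed integer seed controlling initialization; recorded in the fit.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change
#'   below `tol` (default 1e-8) or `max_iter` (default 500) iterations.
#' @return object of class `lctm`: per-class fixed-effect coefficients,
#'   random-effect covariances, residual variances, mixing proportions,
#'   posterior probabilities and modal classes, log-likelihood, BIC
#'   (computed with N = number of homes), convergence flag, and the
#'   log-likelihood trace of the winning run. Classes are relabelled
#'   canonically by decreasing modal size (mean level breaks ties), so
#'   results do not depend on initial labels.
#' @export
lctm <- function(y, K, family = "A", outcome = NULL, restarts = 20,
                 seed = 1, max_iter = 500, tol = 1e-8) {
  if (is.data.frame(y)) {
    if (is.null(outcome)) stop("specify `outcome` for long profile input")
    y <- profile_matrix(y, outcome)
  }
  y <- as.matrix(y)
  if (anyNA(y)) stop("profiles must be complete (24 finite values per home)")
  N <- nrow(y); n <- ncol(y)
  if (N < 2) stop("need at least 2 homes")
  fi <- lctm_family_info(family)
  tt <- seq(0, 1, length.out = n)
  X <- stats::poly(tt, degree = fi$order, raw = TRUE)
  X <- cbind(1, X)
  colnames(X) <- paste0("t^", 0:fi$order)
  Z <- if (fi$q > 0) X[, 1:fi$q, drop = FALSE] else NULL
  set.seed(as.integer(seed))
  best <- NULL
  for (rep_i in seq_len(restarts)) {
    a0 <- kmeanspp_assign(y, K)
    run <- tryCatch(lctm_em(y, X, Z, fi, K, a0, max_iter, tol),
                    error = function(e) NULL)
    if (is.null(run)) next
    better <- is.null(best) ||
      (run$converged && !best$converged) ||
      (run$converged == best$converged && run$logLik > best$logLik)
    if (better) best <- run
  }
  if (is.null(best)) {
    best <- list(beta = matrix(NA_real_, ncol(X), K), G = NULL,
                 sigma2 = rep(NA_real_, K), tau = rep(NA_real_, K),
                 pi = rep(1 / K, K), r = matrix(1 / K, N, K),
                 logLik = NA_real_, trace = numeric(0),
                 converged = FALSE, n_iter = 0L)
  }
  ## canonical label order: decreasing modal count, then mixing, then level
  modal <- max.col(best$r, ties.method = "first")
  cnt <- tabulate(modal, K)
  lvl <- colMeans(X %*% best$beta)
  ord <- order(-cnt, -best$pi, -lvl)
  best$beta <- best$beta[, ord, drop = FALSE]
  best$sigma2 <- best$sigma2[ord]
  best$tau <- best$tau[ord]
  if (!is.null(best$G)) best$G <- best$G[ord]
  best$pi <- best$pi[ord]
  best$r <- best$r[, ord, drop = FALSE]
  modal <- max.col(best$r, ties.method = "first")

  p <- lctm_n_params(family, K)
  bic <- if (is.finite(best$logLik)) -2 * best$logLik + p * log(N) else Inf
  structure(list(
    family = family, order = fi$order, K = K, n_params = p,
    beta = best$beta, G = best$G, sigma2 = best$sigma2, tau = best$tau,
    pi = best$pi, posterior = best$r, modal = modal,
    logLik = best$logLik, BIC = bic,
    converged = best$converged, n_iter = best$n_iter, trace = best$trace,
    y = y, time = tt, X = X, seed = seed, outcome = outcome,
    home_ids = rownames(y)
  ), class = "lctm")
}

#' @export
print.lctm <- function(x, ...) {
  cat(sprintf("Latent-class trajectory model: family %s, K = %d, order %d\n",
              x$family, x$K, x$order))
  cat(sprintf("logLik %.2f | BIC %.2f | %d free parameters | %s (%d iters)\n",
              x$logLik, x$BIC, x$n_params,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat("class sizes (modal):", paste(tabulate(x$modal, x$K), collapse = ", "),
      "| mixing:", paste(sprintf("%.2f", x$pi), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.lctm <- function(object, ...) {
  out <- list(fit = object,
              class_sizes = tabulate(object$modal, object$K),
              coef_scaled = coef(object, scale = "scaled"),
              coef_hours = coef(object, scale = "hours"),
              mean_posterior = vapply(seq_len(object$K), function(k) {
                idx <- object$modal == k
                if (any(idx)) mean(object$posterior[idx, k]) else NA_real_
              }, numeric(1)))
  class(out) <- "summary.lctm"
  out
}

#' @export
print.summary.lctm <- function(x, ...) {
  print(x$fit)
  cat("mean posterior in modal class:",
      paste(sprintf("%.3f", x$mean_posterior), collapse = ", "), "\n")
  cat("fixed-effect coefficients (time scaled to [0,1]):\n")
  print(round(x$coef_scaled, 4))
  invisible(x)
}

#' Fixed-effect trajectory coefficients
#'
#' @param object `lctm` fit.
#' @param scale `"scaled"` for the internal time covariate t = hour/23 in
#'   \[0,1\]; `"hours"` for raw clock hours (coefficient j divided by 23^j).
#' @param ... unused.
#' @return matrix, (order+1) rows x K class columns.
#' @export
coef.lctm <- function(object, scale = c("scaled", "hours"), ...) {
  scale <- match.arg(scale)
  b <- object$beta
  if (scale == "hours") b <- b / 23^(0:object$order)
  colnames(b) <- paste0("class", seq_len(object$K))
  b
}

#' @export
logLik.lctm <- function(object, ...) {
  structure(object$logLik, df = object$n_params, nobs = nrow(object$y),
            class = "logLik")
}

#' Class mean curves
#'
#' @param object `lctm` fit.
#' @param hours clock hours at which to evaluate (default 0:23).
#' @param ... unused.
#' @return matrix, length(hours) x K.
#' @export
predict.lctm <- function(object, hours = 0:23, ...) {
  tt <- hours / 23
  Xn <- cbind(1, stats::poly(tt, degree = object$order, raw = TRUE))
  out <- Xn %*% object$beta
  dimnames(out) <- list(hours, paste0("class", seq_len(object$K)))
  out
}

#' @export
fitted.lctm <- function(object, ...) {
  ## modal-class mean curve per home
  t(object$X %*% object$beta)[object$modal, , drop = FALSE]
}

#' @export
residuals.lctm <- function(object, ...) {
  object$y - fitted(object)
}

#' @export
plot.lctm <- function(x, ...) {
  graphics::matplot(0:23, t(x$y), type = "l", lty = 1,
          col = grDevices::adjustcolor(x$modal + 1, 0.25),
          xlab = "clock hour", ylab = "percent/hour", ...)
  curves <- predict(x)
  graphics::matlines(0:23, curves, lty = 1, lwd = 3, col = seq_len(x$K) + 1)
  graphics::legend("topright", legend = paste0("class ", seq_len(x$K),
                                     " (n=", tabulate(x$modal, x$K), ")"),
         col = seq_len(x$K) + 1, lwd = 3, bty = "n")
  invisible(x)
}

#' Simulate profiles from a fitted trajectory model
#'
#' @param object converged `lctm` fit.
#' @param nsim number of data sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of matrices shaped like the training profiles.
#' @export
simulate.lctm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(object$y); N <- nrow(object$y)
  Z <- if (!is.null(object$G)) object$X[, seq_len(nrow(object$G[[1]])), drop = FALSE]
  out <- lapply(seq_len(nsim), function(s) {
    cls <- sample.int(object$K, N, replace = TRUE, prob = object$pi)
    yy <- matrix(0, N, n)
    for (i in seq_len(N)) {
      k <- cls[i]
      mu <- as.vector(object$X %*% object$beta[, k])
      if (!is.null(Z) && nrow(object$G[[k]]) > 0) {
        L <- chol(symmetrize_psd(object$G[[k]]))
        mu <- mu + as.vector(Z %*% (t(L) %*% stats::rnorm(ncol(Z))))
      }
      yy[i, ] <- mu + stats::rnorm(n, 0, sqrt(object$sigma2[k]))
    }
    attr(yy, "class_truth") <- cls
    yy
  })
  if (nsim == 1) out[[1]] else out
}

#' Grid search over class counts and variance families
#'
#' Fits every requested (family, K) combination, ranks converged fits by
#' BIC, and applies the class-size rule: if the BIC winner has a class with
#' fewer than 2 homes (modal assignment), the search is restricted to fewer
#' classes and repeated. Non-converged fits never enter the ranking.
#'
#' @param y profile matrix (homes x 24) or long profile data.frame with
#'   `outcome`.
#' @param Ks class counts to try (default 1:6).
#' @param families families to try (default A-I).
#' @param outcome outcome name for long input.
#' @param restarts,seed,max_iter,tol passed to [lctm()].
#' @param min_class_n minimum homes per class (default 2).
#' @return object of class `lctm_selection`: `best` fit, `ranking`
#'   data.frame (family, K, logLik, BIC, converged, min_class_n), `fits`.
#' @export
select_lctm <- function(y, Ks = 1:6, families = LETTERS[1:9], outcome = NULL,
                        restarts = 5, seed = 1, max_iter = 500, tol = 1e-8,
                        min_class_n = 2) {
  if (is.data.frame(y)) {
    if (is.null(outcome)) stop("specify `outcome` for long profile input")
    y <- profile_matrix(y, outcome)
  }
  grid <- expand.grid(family = families, K = Ks, stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid))
  rank <- data.frame(family = grid$family, K = grid$K, logLik = NA_real_,
                     BIC = NA_real_, converged = FALSE, min_class_n = NA_integer_,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(lctm(y, K = grid$K[i], family = grid$family[i],
                       restarts = restarts, seed = seed + i,
                       max_iter = max_iter, tol = tol),
                  error = function(e) NULL)
    fits[[i]] <- f
    if (!is.null(f)) {
      rank$logLik[i] <- f$logLik
      rank$BIC[i] <- f$BIC
      rank$converged[i] <- f$converged
      rank$min_class_n[i] <- min(tabulate(f$modal, f$K))
    }
  }
  best_i <- lctm_rank_select(rank, min_class_n)
  structure(list(best = fits[[best_i]],
                 ranking = rank[order(rank$BIC), ],
                 fits = fits),
            class = "lctm_selection")
}

## selection rule on a ranking table: only converged fits are ranked, by
## BIC; if the winner has a class with fewer than min_class_n homes the
## search is restricted to fewer classes and repeated
lctm_rank_select <- function(rank, min_class_n = 2) {
  cand <- which(rank$converged)
  if (length(cand) == 0) {
    stop("no (family, K) combination converged; ranking:\n",
         paste(utils::capture.output(print(rank)), collapse = "\n"))
  }
  repeat {
    best_i <- cand[which.min(rank$BIC[cand])]
    if (rank$min_class_n[best_i] >= min_class_n) return(best_i)
    cand <- cand[rank$K[cand] < rank$K[best_i]]       # choose fewer classes
    if (length(cand) == 0) {
      stop("every admissible model has a class with < ", min_class_n, " homes")
    }
  }
}

#' @export
print.lctm_selection <- function(x, ...) {
  cat("Model selection over", nrow(x$ranking), "fits; chosen:\n")
  print(x$best)
  cat("top of ranking (converged-only eligible):\n")
  print(utils::head(x$ranking, 8), digits = 6)
  invisible(x)
}

#' Modal class assignment
#'
#' @param fit converged `lctm` fit.
#' @param small_threshold classes with at most this many homes are flagged
#'   not interpretable (default 5).
#' @return data.frame `home_id, class, posterior, small_class`.
#' @export
assign_classes <- function(fit, small_threshold = 5) {
  if (!fit$converged) stop("fit did not converge; refusing to assign classes")
  cls <- fit$modal
  sizes <- tabulate(cls, fit$K)
  data.frame(
    home_id = if (!is.null(fit$home_ids)) fit$home_ids
              else sprintf("home%03d", seq_len(nrow(fit$y))),
    class = cls,
    posterior = fit$posterior[cbind(seq_along(cls), cls)],
    small_class = sizes[cls] <= small_threshold,
    stringsAsFactors = FALSE
  )
}
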