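# Spatio-temporal imputation: lag regression with spatially correlated
# within-day errors,
#
#   y_{i,t} = beta0 + beta1 * y_{i,t-1} + e_{i,t}
#
# where within each day the errors across monitors have exponential
# covariance sill * exp(-d / range) and days are independent given the lag.
# Coefficients are estimated by generalized least squares; the covariance
# parameters by restricted maximum likelihood on the GLS residuals, profiled
# over the sill, iterating the two steps to convergence.

#' Fit the spatio-temporal lag model
#'
#' Uses all monitor-day pairs with the day and its within-season predecessor
#' both observed. Estimation alternates (a) generalized least squares for
#' (beta0, beta1) given the spatial error covariance, and (b) restricted
#' maximum likelihood for (sill, range) given the coefficients, with the
#' sill profiled analytically and the range found by one-dimensional search
#' on a subsample of days.
#'
#' @param grid an \code{hi_grid}.
#' @param max_iter maximum GLS/REML alternations.
#' @param cov_days number of (evenly spaced) days used in the covariance
#'   likelihood; covariance estimates stabilize long before all days are
#'   used.
#' @param range_bounds search interval for the range, km.
#' @return a \code{spatiotemporal_fit}: list with \code{beta0}, \code{beta1},
#'   \code{se} (GLS standard errors), \code{sill}, \code{range},
#'   \code{n_pairs}, \code{iterations}.
#' @export
fit_spatiotemporal <- function(grid, max_iter = 5, cov_days = 600,
                               range_bounds = c(1, 10000)) {
  vals <- grid$values
  cal <- grid$calendar
  dmat <- network_distances(grid$network)
  lag_days <- which(cal$season_day > 1L)
  day_idx <- list()
  for (t in lag_days) {
    ok <- which(!is.na(vals[, t]) & !is.na(vals[, t - 1L]))
    if (length(ok)) day_idx[[as.character(t)]] <- ok
  }
  if (!length(day_idx)) stop("no usable lag pairs")
  use_t <- as.integer(names(day_idx))
  n_pairs <- sum(lengths(day_idx))

  # OLS start
  yv <- unlist(lapply(use_t, function(t) vals[day_idx[[as.character(t)]], t]))
  xv <- unlist(lapply(use_t, function(t) {
    vals[day_idx[[as.character(t)]], t - 1L]
  }))
  beta <- stats::coef(stats::lm(yv ~ xv))
  names(beta) <- NULL

  cov_t <- use_t[unique(pmax(1L, round(seq(1L, length(use_t),
                                           length.out = min(cov_days,
                                                            length(use_t))))))]
  sill <- stats::var(yv - beta[1L] - beta[2L] * xv)
  range_km <- exp(mean(log(range_bounds)))
  se <- c(NA_real_, NA_real_)
  iter_used <- 0L
  for (iter in seq_len(max_iter)) {
    iter_used <- iter
    # (b) covariance given beta
    rll <- function(lr) {
      r <- exp(lr)
      ld <- 0
      q <- 0
      N <- 0
      for (t in cov_t) {
        ix <- day_idx[[as.character(t)]]
        n_t <- length(ix)
        res <- vals[ix, t] - beta[1L] - beta[2L] * vals[ix, t - 1L]
        if (n_t == 1L) {
          ld <- ld + 0
          q <- q + res^2
          N <- N + 1L
          next
        }
        V <- exp(-dmat[ix, ix, drop = FALSE] / r)
        diag(V) <- diag(V) + 1e-8
        ch <- tryCatch(chol(V), error = function(e) NULL)
        if (is.null(ch)) return(-1e10)
        ld <- ld + 2 * sum(log(diag(ch)))
        z <- forwardsolve(t(ch), res)
        q <- q + sum(z^2)
        N <- N + n_t
      }
      shat <- q / N
      if (shat <= 0) return(-1e10)
      -0.5 * (N * log(shat) + ld)
    }
    opt <- stats::optimize(function(lr) -rll(lr), interval = log(range_bounds),
                           tol = 0.02)
    range_new <- exp(opt$minimum)
    # recompute profiled sill at the chosen range over cov_t
    q <- 0
    N <- 0
    for (t in cov_t) {
      ix <- day_idx[[as.character(t)]]
      res <- vals[ix, t] - beta[1L] - beta[2L] * vals[ix, t - 1L]
      if (length(ix) == 1L) {
        q <- q + res^2
        N <- N + 1L
        next
      }
      V <- exp(-dmat[ix, ix, drop = FALSE] / range_new)
      diag(V) <- diag(V) + 1e-8
      z <- forwardsolve(t(chol(V)), res)
      q <- q + sum(z^2)
      N <- N + length(ix)
    }
    sill_new <- max(q / N, 1e-10)
    # (a) GLS for beta given covariance (correlation matters, sill cancels)
    XtX <- matrix(0, 2, 2)
    Xty <- numeric(2)
    for (t in use_t) {
      ix <- day_idx[[as.character(t)]]
      X <- cbind(1, vals[ix, t - 1L])
      yt <- vals[ix, t]
      if (length(ix) == 1L) {
        XtX <- XtX + crossprod(X)
        Xty <- Xty + as.numeric(crossprod(X, yt))
        next
      }
      V <- exp(-dmat[ix, ix, drop = FALSE] / range_new)
      diag(V) <- diag(V) + 1e-8
      ch <- chol(V)
      Xw <- backsolve(ch, forwardsolve(t(ch), X), transpose = FALSE)
      XtX <- XtX + crossprod(X, Xw)
      Xty <- Xty + as.numeric(crossprod(Xw, yt))
    }
    beta_new <- solve(XtX, Xty)
    se <- sqrt(diag(solve(XtX)) * sill_new)
    done <- max(abs(beta_new - beta)) < 1e-5 &&
      abs(log(range_new / range_km)) < 1e-3
    beta <- beta_new
    sill <- sill_new
    range_km <- range_new
    if (done) break
  }
  structure(list(beta0 = beta[1L], beta1 = beta[2L], se = se, sill = sill,
                 range = range_km, n_pairs = n_pairs,
                 iterations = iter_used),
            class = "spatiotemporal_fit")
}

#' @export
print.spatiotemporal_fit <- function(x, ...) {
  cat(sprintf(
    "<spatiotemporal_fit> beta0=%.3f (se %.3f), beta1=%.4f (se %.4f), sill=%.2f F^2, range=%.0f km, %d lag pairs\n",
    x$beta0, x$se[1L], x$beta1, x$se[2L], x$sill, x$range, x$n_pairs))
  invisible(x)
}

#' Impute missing cells with the spatio-temporal model
#'
#' Processes each warm season chronologically. The first day of a season has
#' no lag and falls back to the per-day spatial model (ordinary kriging, or
#' monthly means when fewer than two monitors recorded). On every other day,
#' a missing monitor is predicted as \code{beta0 + beta1 * lag} plus the
#' simple-kriging interpolation (known mean zero) of that day's observed lag
#' residuals under the fitted exponential covariance. Lags use observed
#' values when present and the previous day's imputed value otherwise.
#' Observed cells are never altered.
#'
#' @param grid an \code{hi_grid}.
#' @param fit a \code{spatiotemporal_fit} (defaults to fitting on
#'   \code{grid}).
#' @return the completed \code{hi_grid} with a \code{"diagnostics"}
#'   attribute (the fit plus first-day fallback counts).
#' @export
impute_spatiotemporal <- function(grid, fit = fit_spatiotemporal(grid)) {
  vals <- grid$values
  cal <- grid$calendar
  net <- grid$network
  dmat <- network_distances(net)
  mm <- tryCatch(monthly_mean_table(grid), error = function(e) NULL)
  b0 <- fit$beta0
  b1 <- fit$beta1
  n_first_fallback <- 0L
  for (t in seq_len(ncol(vals))) {
    miss <- which(is.na(vals[, t]))
    if (!length(miss)) next
    obs <- which(!is.na(grid$values[, t]))
    if (cal$season_day[t] == 1L) {
      filled <- FALSE
      if (length(obs) >= 2L) {
        f <- tryCatch(
          fit_exp_reml(grid$values[obs, t], dmat[obs, obs, drop = FALSE]),
          error = function(e) NULL)
        if (!is.null(f)) {
          pred <- krige_day(
            f,
            data.frame(longitude = net$longitude[obs],
                       latitude = net$latitude[obs],
                       value = grid$values[obs, t]),
            data.frame(longitude = net$longitude[miss],
                       latitude = net$latitude[miss]))
          vals[miss, t] <- as.numeric(pred)
          filled <- TRUE
        }
      }
      if (!filled) {
        if (is.null(mm)) stop("cannot impute first season day ", t,
                              ": no spatial fit and no monthly means")
        vals[miss, t] <- mm[miss, as.character(cal$month[t])]
        n_first_fallback <- n_first_fallback + 1L
      }
      next
    }
    lag <- vals[, t - 1L]  # completed up to t-1 by forward processing
    pred <- b0 + b1 * lag[miss]
    if (length(obs)) {
      res <- grid$values[obs, t] - (b0 + b1 * lag[obs])
      V <- exp(-dmat[obs, obs, drop = FALSE] / fit$range)
      diag(V) <- diag(V) + 1e-8
      s0 <- exp(-dmat[miss, obs, drop = FALSE] / fit$range)
      pred <- pred + as.numeric(s0 %*% solve(V, res))
    }
    vals[miss, t] <- pred
  }
  out <- hi_grid(vals, cal, net)
  attr(out, "diagnostics") <- list(fit = fit,
                                   n_first_day_fallbacks = n_first_fallback)
  out
}
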