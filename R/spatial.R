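# Spatial imputation: per-day ordinary kriging under an exponential
# covariance fitted by restricted maximum likelihood, with a monitor-specific
# monthly-mean fallback for days on which fewer than two monitors recorded.

exp_cov <- function(d, sill, range, nugget = 0) {
  v <- sill * exp(-d / range)
  if (nugget > 0) v <- v + nugget * (d == 0)
  v
}

#' Fit the exponential spatial model for one day
#'
#' Restricted maximum likelihood estimation of (sill, range) for the
#' observations of a single day under a constant unknown mean and covariance
#' \code{sill * exp(-d / range) + nugget * 1(d = 0)}. The sill is profiled
#' out analytically; the range is found by one-dimensional search. The
#' nugget is a fixed ratio of the sill (default 0).
#'
#' @param grid an \code{hi_grid}.
#' @param day_t day index (column) to fit.
#' @param nugget_ratio nugget as a fraction of the sill (default 0).
#' @param range_bounds search interval for the range, km.
#' @return a \code{spatial_day_fit}: list with \code{t}, \code{sill},
#'   \code{range}, \code{nugget}, \code{mu} (GLS mean), \code{observed}
#'   (monitor ids), \code{reml} (maximized restricted log-likelihood).
#'   A day with fewer than two observed monitors raises a condition of class
#'   \code{"hotspell_fallback_required"}.
#' @export
fit_spatial_day <- function(grid, day_t, nugget_ratio = 0,
                            range_bounds = c(1, 10000)) {
  y <- grid$values[, day_t]
  obs <- which(!is.na(y))
  if (length(obs) < 2L) {
    stop(errorCondition(
      paste0("day ", day_t, " has ", length(obs),
             " observed monitor(s); fallback required"),
      class = "hotspell_fallback_required"))
  }
  d <- network_distances(grid$network)[obs, obs, drop = FALSE]
  fit <- fit_exp_reml(y[obs], d, nugget_ratio, range_bounds)
  structure(c(list(t = day_t, observed = rownames(grid$values)[obs]), fit),
            class = "spatial_day_fit")
}

# REML for y ~ N(mu 1, sill * (exp(-d/range) + ratio * I)); profile sill.
fit_exp_reml <- function(y, d, nugget_ratio = 0, range_bounds = c(1, 10000)) {
  n <- length(y)
  if (stats::var(y) < 1e-12) {
    return(list(sill = 0, range = mean(range_bounds), nugget = 0,
                mu = mean(y), reml = Inf))
  }
  rll <- function(lr) {
    r <- exp(lr)
    V <- exp(-d / r)
    if (nugget_ratio > 0) diag(V) <- diag(V) + nugget_ratio
    diag(V) <- diag(V) + 1e-8
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    ldV <- 2 * sum(log(diag(ch)))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    xvx <- sum(Vi_1)
    mu <- sum(Vi_y) / xvx
    q <- sum(y * Vi_y) - mu^2 * xvx
    shat <- q / (n - 1)
    if (shat <= 0) return(-1e10)
    -0.5 * ((n - 1) * log(shat) + ldV + log(xvx))
  }
  opt <- stats::optimize(function(lr) -rll(lr),
                         interval = log(range_bounds), tol = 0.02)
  lr <- opt$minimum
  r <- exp(lr)
  V <- exp(-d / r)
  if (nugget_ratio > 0) diag(V) <- diag(V) + nugget_ratio
  diag(V) <- diag(V) + 1e-8
  ch <- chol(V)
  Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  xvx <- sum(Vi_1)
  mu <- sum(Vi_y) / xvx
  sill <- max((sum(y * Vi_y) - mu^2 * xvx) / (n - 1), 0)
  if (!is.finite(sill) || !is.finite(mu)) stop("spatial REML failed")
  list(sill = sill, range = r, nugget = sill * nugget_ratio, mu = mu,
       reml = -opt$objective)
}

#' Ordinary kriging prediction
#'
#' Solves the ordinary-kriging system (weights constrained to sum to one,
#' unknown constant mean) under the day fit's exponential covariance and
#' predicts at target locations. With zero nugget the predictor honors the
#' data exactly at observed sites, and a constant field is reproduced
#' exactly everywhere.
#'
#' @param fit a \code{spatial_day_fit} (or any list with \code{sill},
#'   \code{range}, \code{nugget}).
#' @param observations data frame with columns \code{longitude},
#'   \code{latitude}, \code{value} (at least 2 rows).
#' @param target_locations data frame with columns \code{longitude},
#'   \code{latitude}.
#' @return numeric predictions (degrees F), one per target row, with the
#'   kriging weight matrix (targets x observations) as attribute
#'   \code{"weights"}.
#' @export
krige_day <- function(fit, observations, target_locations) {
  n <- nrow(observations)
  if (n < 2L) stop("ordinary kriging needs at least 2 observations")
  pts <- rbind(observations[, c("longitude", "latitude")],
               target_locations[, c("longitude", "latitude")])
  dup <- duplicated(observations[, c("longitude", "latitude")])
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicated observation coordinates (%.5f, %.5f)",
                 observations$longitude[i], observations$latitude[i]))
  }
  D <- haversine_matrix(pts$longitude, pts$latitude)
  y <- observations$value
  m <- nrow(target_locations)
  if (fit$sill <= 1e-12) {
    # degenerate (constant) field: equal weights, prediction is the mean
    w <- matrix(1 / n, m, n)
    out <- rep(mean(y), m)
    attr(out, "weights") <- w
    return(out)
  }
  S <- exp_cov(D[seq_len(n), seq_len(n), drop = FALSE],
               fit$sill, fit$range, fit$nugget)
  # tiny relative jitter keeps long-range (near-constant) covariances solvable
  diag(S) <- diag(S) + 1e-10 * fit$sill
  K <- rbind(cbind(S, 1), c(rep(1, n), 0))
  s0 <- fit$sill * exp(-D[seq_len(n), n + seq_len(m), drop = FALSE] /
                         fit$range)
  rhs <- rbind(s0, rep(1, m))
  sol <- tryCatch(solve(K, rhs), error = function(e) {
    stop("singular ordinary-kriging system (check for duplicated ",
         "coordinates)")
  })
  w <- t(sol[seq_len(n), , drop = FALSE])
  out <- as.numeric(w %*% y)
  attr(out, "weights") <- w
  out
}

monthly_mean_table <- function(grid) {
  months <- sort(unique(grid$calendar$month))
  tab <- sapply(months, function(m) {
    cols <- grid$calendar$month == m
    rowMeans(grid$values[, cols, drop = FALSE], na.rm = TRUE)
  })
  colnames(tab) <- months
  if (any(!is.finite(tab))) {
    bad <- which(!is.finite(tab), arr.ind = TRUE)
    stop("monthly-mean fallback undefined: monitor ",
         rownames(grid$values)[bad[1L, 1L]], " has no observation in month ",
         months[bad[1L, 2L]])
  }
  tab
}

#' Impute missing cells by per-day ordinary kriging
#'
#' For each day with at least two observed monitors, fits the exponential
#' model by REML and predicts every missing monitor by ordinary kriging from
#' that day's observations. Days with fewer than two observed monitors fall
#' back to each missing monitor's own all-years monthly mean of observed
#' values. Days whose REML optimization fails reuse pooled parameters (the
#' median sill and range over successfully fitted days of the same calendar
#' month).
#'
#' A day whose REML range estimate collapses onto the search boundary is a
#' degenerate single-day fit (the exponential model cannot separate signal
#' from noise on that day's draw) and is treated as an optimizer failure,
#' i.e. it also receives the pooled monthly parameters.
#'
#' @param grid an \code{hi_grid}.
#' @param nugget_ratio passed to \code{\link{fit_spatial_day}}.
#' @param range_bounds REML search interval for the range, km; estimates in
#'   the outer boundary zones (below 5x the lower bound or above 0.9x the
#'   upper) are replaced by pooled parameters.
#' @return the completed \code{hi_grid}, with a \code{"diagnostics"}
#'   attribute listing per-day parameters and counts of fallback days
#'   (\code{n_fallback_days}) and pooled-parameter days
#'   (\code{n_pooled_days}).
#' @export
impute_spatial <- function(grid, nugget_ratio = 0,
                           range_bounds = c(1, 10000)) {
  vals <- grid$values
  cal <- grid$calendar
  mm <- monthly_mean_table(grid)
  dmat <- network_distances(grid$network)
  T <- ncol(vals)
  params <- matrix(NA_real_, T, 2, dimnames = list(NULL, c("sill", "range")))
  fallback_days <- integer(0)
  failed_days <- integer(0)
  fits <- vector("list", T)
  raw_fits <- vector("list", T)
  need <- which(colSums(is.na(vals)) > 0L)
  for (t in need) {
    obs <- which(!is.na(vals[, t]))
    if (length(obs) < 2L) {
      fallback_days <- c(fallback_days, t)
      next
    }
    f <- tryCatch(
      fit_exp_reml(vals[obs, t], dmat[obs, obs, drop = FALSE], nugget_ratio,
                   range_bounds),
      error = function(e) NULL)
    raw_fits[[t]] <- f
    if (!is.null(f) && f$sill > 0 &&
        (f$range <= 5 * range_bounds[1L] ||
           f$range >= 0.9 * range_bounds[2L])) {
      f <- NULL  # boundary estimate: degenerate fit, use pooled parameters
    }
    if (is.null(f)) {
      failed_days <- c(failed_days, t)
    } else {
      params[t, ] <- c(f$sill, f$range)
      fits[[t]] <- f
    }
  }
  # pooled monthly medians for failed optimizations
  if (length(failed_days)) {
    for (t in failed_days) {
      same_month <- which(cal$month == cal$month[t])
      ok <- same_month[is.finite(params[same_month, 1L])]
      if (!length(ok)) ok <- which(is.finite(params[, 1L]))
      if (length(ok)) {
        fits[[t]] <- list(sill = stats::median(params[ok, 1L]),
                          range = stats::median(params[ok, 2L]))
        fits[[t]]$nugget <- fits[[t]]$sill * nugget_ratio
      } else if (!is.null(raw_fits[[t]])) {
        fits[[t]] <- raw_fits[[t]]  # nothing to pool from: keep the raw fit
      } else {
        fallback_days <- c(fallback_days, t)  # monthly means as last resort
      }
    }
  }
  net <- grid$network
  for (t in seq_len(T)) {
    miss <- which(is.na(vals[, t]))
    if (!length(miss)) next
    if (t %in% fallback_days) {
      vals[miss, t] <- mm[miss, as.character(cal$month[t])]
    } else {
      obs <- which(!is.na(grid$values[, t]))
      pred <- krige_day(
        fits[[t]],
        data.frame(longitude = net$longitude[obs],
                   latitude = net$latitude[obs],
                   value = grid$values[obs, t]),
        data.frame(longitude = net$longitude[miss],
                   latitude = net$latitude[miss]))
      vals[miss, t] <- as.numeric(pred)
    }
  }
  out <- hi_grid(vals, cal, grid$network)
  attr(out, "diagnostics") <- list(
    params = data.frame(t = seq_len(T), sill = params[, 1L],
                        range = params[, 2L]),
    n_fallback_days = length(fallback_days),
    fallback_days = fallback_days,
    n_pooled_days = length(failed_days))
  out
}
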