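# Temporal imputation: per-monitor additive latent Gaussian model
#
#   y_t = mu + f1(t) + f2(year) + f3(season day) + e_t,  e_t ~ N(0, sigma^2)
#
# f1 is a stationary AR(1) over the running day index (long-term/short-term
# temporal changes), f2 a second-order random walk over year (yearly trend),
# f3 a second-order random walk over day 1..183 of the season (within-season
# shape, shared across years). All components have sparse precision
# matrices; hyperparameters (AR coefficient, component precisions, noise
# variance) are estimated by maximizing the marginal likelihood with the
# latent field integrated out, and imputation uses the posterior mean.

rw2_structure <- function(n) {
  if (n < 3L) return(NULL)
  D <- diff(diag(n), differences = 2)
  R <- Matrix::Matrix(crossprod(D), sparse = TRUE)
  ev <- eigen(as.matrix(R), symmetric = TRUE, only.values = TRUE)$values
  list(R = methods::as(R, "generalMatrix"),
       lgdet = sum(log(ev[ev > 1e-9])), rank = n - 2L)
}

ar1_precision <- function(n, phi, tau) {
  # stationary AR(1) with marginal variance 1/tau
  scale <- tau / (1 - phi^2)
  i <- c(seq_len(n), seq_len(n - 1L), 2L:n)
  j <- c(seq_len(n), 2L:n, seq_len(n - 1L))
  x <- c(1, rep(1 + phi^2, n - 2L), 1, rep(-phi, 2L * (n - 1L))) * scale
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

ar1_lgdet <- function(n, phi, tau) {
  n * log(tau) - (n - 1) * log(1 - phi^2)
}

#' Fit the temporal latent Gaussian model for one monitor
#'
#' Maximizes the marginal likelihood over (AR coefficient, AR precision,
#' year-RW2 precision, day-of-season-RW2 precision, noise variance) and
#' returns posterior-mean latent components. The year component is dropped
#' (\code{year_effect_dropped}) when only one season is present or when its
#' estimated variance collapses to the boundary (below \code{1e-8} of the
#' data variance) or the fit fails with it included; the model is then refit
#' without it.
#'
#' @param grid an \code{hi_grid}.
#' @param monitor_id a monitor id present in the grid.
#' @param control list; \code{maxit} for the Nelder-Mead hyperparameter
#'   search (default 300).
#' @return an object of class \code{temporal_fit} with elements
#'   \code{fitted} (posterior-mean prediction at every day index),
#'   \code{components} (\code{mu}, \code{f1}, \code{f2}, \code{f3}),
#'   \code{hyper} (phi, component variances, \code{sigma2}),
#'   \code{year_effect_dropped}, \code{n_obs}, \code{converged}.
#' @export
fit_temporal <- function(grid, monitor_id, control = list()) {
  maxit <- control$maxit %||% 300L
  row <- match(monitor_id, rownames(grid$values))
  if (is.na(row)) stop("unknown monitor id: ", monitor_id)
  y <- grid$values[row, ]
  obs <- which(!is.na(y))
  if (length(obs) < 30L) {
    stop("monitor ", monitor_id, " has only ", length(obs),
         " observed days; temporal model unidentifiable")
  }
  cal <- grid$calendar
  J <- max(cal$year_index)
  seasons_obs <- length(unique(cal$year_index[obs]))
  use_year <- J >= 3L && seasons_obs >= 2L
  fit <- try(fit_temporal_engine(y, obs, cal, J, use_year, maxit),
             silent = TRUE)
  if (use_year && (inherits(fit, "try-error") || fit$drop_year)) {
    fit <- fit_temporal_engine(y, obs, cal, J, FALSE, maxit)
    fit$year_effect_dropped <- TRUE
  } else {
    if (inherits(fit, "try-error")) stop(attr(fit, "condition")$message)
    fit$year_effect_dropped <- !use_year
  }
  fit$monitor_id <- monitor_id
  class(fit) <- "temporal_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fit_temporal_engine <- function(y, obs, cal, J, use_year, maxit) {
  T <- length(y)
  yo <- y[obs]
  n <- length(yo)
  ybar <- mean(yo)
  yc <- yo - ybar
  vy <- max(stats::var(yc), 1e-10)

  nd <- 183L
  rw_d <- rw2_structure(nd)
  rw_y <- if (use_year) rw2_structure(J) else NULL

  # latent layout: f1 (T) | [f2 (J)] | f3 (183) | mu (1)
  off_f2 <- T
  off_f3 <- T + if (use_year) J else 0L
  off_mu <- off_f3 + nd
  p <- off_mu + 1L

  cols <- c(obs,
            if (use_year) off_f2 + cal$year_index[obs],
            off_f3 + cal$season_day[obs],
            rep(off_mu + 1L, n))
  rows <- rep(seq_len(n), times = if (use_year) 4L else 3L)
  A <- Matrix::sparseMatrix(i = rows, j = cols, x = 1, dims = c(n, p))
  AtA <- Matrix::crossprod(A)
  Aty <- as.numeric(Matrix::crossprod(A, yc))
  yy <- sum(yc^2)

  # soft sum-to-zero constraints on the intrinsic RW2 blocks
  kc <- 1e6
  cons <- list(off_f3 + seq_len(nd))
  if (use_year) cons <- c(cons, list(off_f2 + seq_len(J)))
  Qc <- Reduce(`+`, lapply(cons, function(ix) {
    v <- Matrix::sparseVector(rep(1, length(ix)), ix, p)
    kc * Matrix::tcrossprod(methods::as(v, "CsparseMatrix"))
  }))

  mu_prec <- 1e-8

  # Assemble the posterior precision once to fix the sparsity pattern, then
  # refill @x in place on every likelihood evaluation (the pattern is
  # hyperparameter-independent).
  build_Q_slow <- function(phi, tau1, tau2, tau3) {
    Q1 <- ar1_precision(T, phi, tau1)
    blocks <- list(Q1)
    if (use_year) blocks <- c(blocks, list(tau2 * rw_y$R))
    blocks <- c(blocks, list(tau3 * rw_d$R),
                Matrix::Matrix(mu_prec, 1, 1, sparse = TRUE))
    Matrix::bdiag(blocks)
  }
  P <- Matrix::forceSymmetric(build_Q_slow(0.5, 1, 1, 1) + AtA + Qc)
  P <- methods::as(P, "CsparseMatrix")
  key_of <- function(M) {
    M <- Matrix::forceSymmetric(methods::as(M, "CsparseMatrix"), uplo = "U")
    col <- rep.int(seq_len(ncol(M)), diff(M@p))
    list(key = as.numeric(M@i) * p + col, x = M@x)
  }
  kP <- key_of(P)
  map_of <- function(M) {
    k <- key_of(M)
    list(ix = match(k$key, kP$key), x = k$x)
  }
  m_AtA <- map_of(AtA)
  offset_block <- function(M, off) {
    M <- methods::as(methods::as(M, "CsparseMatrix"), "TsparseMatrix")
    Matrix::sparseMatrix(i = M@i + 1L + off, j = M@j + 1L + off, x = M@x,
                         dims = c(p, p))
  }
  m_Rd <- map_of(offset_block(rw_d$R, off_f3))
  m_Ry <- if (use_year) map_of(offset_block(rw_y$R, off_f2)) else NULL
  stopifnot(!anyNA(m_AtA$ix), !anyNA(m_Rd$ix),
            is.null(m_Ry) || !anyNA(m_Ry$ix))
  base_x <- numeric(length(kP$x))
  kQc <- map_of(Qc)
  base_x[kQc$ix] <- kQc$x
  i_mu <- match((off_mu) * p + (off_mu + 1L), kP$key)  # 0-based row key
  base_x[i_mu] <- base_x[i_mu] + mu_prec
  # AR1 block entry positions: diagonal ends, diagonal middle, off-diagonal
  i_d <- match((seq_len(T) - 1) * p + seq_len(T), kP$key)
  i_o <- match((seq_len(T - 1L) - 1) * p + (seq_len(T - 1L) + 1L), kP$key)
  i_d_end <- i_d[c(1L, T)]
  i_d_mid <- i_d[-c(1L, T)]

  fill_Q <- function(phi, tau1, tau2, tau3, s2) {
    x <- base_x
    x[m_AtA$ix] <- x[m_AtA$ix] + m_AtA$x / s2
    x[m_Rd$ix] <- x[m_Rd$ix] + tau3 * m_Rd$x
    if (use_year) x[m_Ry$ix] <- x[m_Ry$ix] + tau2 * m_Ry$x
    sc <- tau1 / (1 - phi^2)
    x[i_d_end] <- x[i_d_end] + sc
    x[i_d_mid] <- x[i_d_mid] + sc * (1 + phi^2)
    x[i_o] <- x[i_o] - sc * phi
    P@x <- x
    P
  }

  lgdet_prior <- function(th) {
    phi <- tanh(th[2L])
    out <- ar1_lgdet(T, phi, exp(th[1L]))
    if (use_year) out <- out + rw_y$rank * th[3L] + rw_y$lgdet
    k3 <- if (use_year) 4L else 3L
    out + rw_d$rank * th[k3] + rw_d$lgdet
  }

  th_parts <- function(th) {
    list(phi = tanh(th[2L]), tau1 = exp(th[1L]),
         tau2 = if (use_year) exp(th[3L]) else 1,
         tau3 = exp(th[if (use_year) 4L else 3L]),
         s2 = exp(th[length(th)]))
  }

  symb <- Matrix::Cholesky(fill_Q(0.5, 1, 1, 1, 1), LDL = FALSE,
                           super = FALSE)
  nll <- function(th) {
    h <- th_parts(th)
    if (!all(is.finite(th)) || h$s2 < 1e-9) return(1e10)
    Qp <- fill_Q(h$phi, h$tau1, h$tau2, h$tau3, h$s2)
    ch <- tryCatch(Matrix::update(symb, Qp), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    ld_post <- 2 * Matrix::determinant(ch, logarithm = TRUE,
                                       sqrt = TRUE)$modulus
    b <- Aty / h$s2
    m <- as.numeric(Matrix::solve(ch, b, system = "A"))
    quad <- yy / h$s2 - sum(b * m)
    ll <- 0.5 * lgdet_prior(th) - 0.5 * ld_post - 0.5 * n * log(h$s2) -
      0.5 * quad
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  th0 <- c(log(1 / (0.6 * vy)), atanh(0.6),
           if (use_year) log(1 / max(0.05 * vy, 1e-4)),
           log(1 / max(0.5 * vy, 1e-4)),
           log(0.3 * vy))
  opt <- stats::optim(th0, nll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-6))
  th <- opt$par
  h <- th_parts(th)
  s2 <- max(h$s2, 1e-9)
  ch <- Matrix::update(symb, fill_Q(h$phi, h$tau1, h$tau2, h$tau3, s2))
  m <- as.numeric(Matrix::solve(ch, Aty / s2, system = "A"))

  f1 <- m[seq_len(T)]
  f2 <- if (use_year) m[off_f2 + seq_len(J)] else rep(0, J)
  f3 <- m[off_f3 + seq_len(nd)]
  mu <- m[off_mu + 1L] + ybar
  fitted <- mu + f1 + f2[cal$year_index] + f3[cal$season_day]

  var2 <- if (use_year) 1 / exp(th[3L]) else 0
  list(
    fitted = fitted,
    components = list(mu = mu, f1 = f1, f2 = f2, f3 = f3),
    hyper = list(
      phi = tanh(th[2L]),
      var_ar = 1 / exp(th[1L]),
      var_year = var2,
      var_doy = 1 / exp(th[if (use_year) 4L else 3L]),
      sigma2 = s2
    ),
    n_obs = n,
    converged = opt$convergence == 0L,
    drop_year = use_year && var2 <= 1e-8 * vy
  )
}

#' @export
print.temporal_fit <- function(x, ...) {
  cat(sprintf(
    "<temporal_fit> monitor %s: n=%d, phi=%.3f, sigma2=%.3f%s\n",
    x$monitor_id, x$n_obs, x$hyper$phi, x$hyper$sigma2,
    if (x$year_effect_dropped) ", year effect dropped" else ""))
  invisible(x)
}

#' Impute missing cells with the temporal model
#'
#' Fits the per-monitor temporal model and replaces every missing cell with
#' the posterior-mean prediction at its (day index, year, day-of-season);
#' observed cells are never modified.
#'
#' @param grid an \code{hi_grid}.
#' @param control passed to \code{\link{fit_temporal}}.
#' @param verbose emit a progress message per monitor.
#' @return the completed \code{hi_grid}, with a \code{"diagnostics"}
#'   attribute: data frame of per-monitor hyperparameters and fallback flags.
#' @export
impute_temporal <- function(grid, control = list(), verbose = FALSE) {
  vals <- grid$values
  diags <- vector("list", nrow(vals))
  for (i in seq_len(nrow(vals))) {
    id <- rownames(vals)[i]
    miss <- is.na(vals[i, ])
    if (!any(miss)) next
    fit <- fit_temporal(grid, id, control)
    vals[i, miss] <- fit$fitted[miss]
    diags[[i]] <- data.frame(
      monitor_id = id, n_obs = fit$n_obs, phi = fit$hyper$phi,
      sigma2 = fit$hyper$sigma2, var_year = fit$hyper$var_year,
      year_effect_dropped = fit$year_effect_dropped,
      converged = fit$converged, stringsAsFactors = FALSE)
    if (verbose) message("impute_temporal: ", id, " done")
  }
  out <- hi_grid(vals, grid$calendar, grid$network)
  attr(out, "diagnostics") <- do.call(rbind, diags)
  out
}
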