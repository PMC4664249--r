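# Hold-out validation: day-stratified 10% sample, RMSPE comparison of
# imputation methods overall, on extreme values, and per monitor.

#' Draw a day-stratified hold-out sample
#'
#' Within each day (stratum), rounds \code{fraction} times the number of
#' observed monitors to the nearest integer (round half to even) and samples
#' that many observed cells without replacement. Only originally observed
#' cells can be held out.
#'
#' @param grid an \code{hi_grid}.
#' @param fraction hold-out fraction in (0, 1); default 0.10.
#' @param seed integer seed; the draw is deterministic given it.
#' @return a \code{holdout_sample}: list with \code{cells} (data frame
#'   \code{monitor_id,date,row,col,true_hi_f}), \code{fraction},
#'   \code{seed}.
#' @export
draw_holdout <- function(grid, fraction = 0.10, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  vals <- grid$values
  with_seed(seed, {
    rows <- integer(0)
    cols <- integer(0)
    for (t in seq_len(ncol(vals))) {
      obs <- which(!is.na(vals[, t]))
      k <- round(fraction * length(obs))
      if (k >= 1L) {
        pick <- if (length(obs) == 1L) obs else sample(obs, k)
        rows <- c(rows, pick)
        cols <- c(cols, rep.int(t, k))
      }
    }
    cells <- data.frame(
      monitor_id = rownames(vals)[rows],
      date = grid$calendar$date[cols],
      row = rows, col = cols,
      true_hi_f = vals[cbind(rows, cols)],
      stringsAsFactors = FALSE)
    structure(list(cells = cells, fraction = fraction, seed = seed),
              class = "holdout_sample")
  })
}

#' Remove held-out cells from a grid
#' @param grid an \code{hi_grid}.
#' @param holdout a \code{holdout_sample} drawn from it.
#' @return the reduced \code{hi_grid}.
#' @export
mask_holdout <- function(grid, holdout) {
  vals <- grid$values
  vals[cbind(holdout$cells$row, holdout$cells$col)] <- NA_real_
  hi_grid(vals, grid$calendar, grid$network)
}

#' Root mean squared prediction error
#'
#' @param predictions,truths equal-length paired numeric vectors.
#' @param subset_threshold_f if given, restrict to pairs whose \emph{true}
#'   value strictly exceeds this (degrees F).
#' @return RMSPE in degrees F; \code{NA} (with a warning) when the subset is
#'   empty.
#' @export
rmspe <- function(predictions, truths, subset_threshold_f = NULL) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  keep <- rep(TRUE, length(truths))
  if (!is.null(subset_threshold_f)) keep <- truths > subset_threshold_f
  if (!any(keep)) {
    warning("no qualifying pairs for RMSPE subset")
    return(NA_real_)
  }
  sqrt(mean((predictions[keep] - truths[keep])^2))
}

builtin_imputers <- function() {
  list(temporal = impute_temporal,
       spatial = impute_spatial,
       spatiotemporal = function(g) impute_spatiotemporal(g))
}

#' Compare imputation methods by stratified hold-out
#'
#' Draws one day-stratified hold-out sample, refits every method on the
#' reduced grid, and scores predictions at the held-out cells against the
#' withheld observed values: overall RMSPE, RMSPE restricted to true values
#' above \code{extreme_threshold_f}, per-monitor RMSPE, and per-monitor
#' best/worst method flags. All methods are scored against the same single
#' draw (paired comparison).
#'
#' @param grid an \code{hi_grid} (the observed study grid).
#' @param methods character vector naming built-in imputers
#'   (\code{"temporal"}, \code{"spatial"}, \code{"spatiotemporal"}) and/or a
#'   named list of functions \code{function(hi_grid) -> completed hi_grid}.
#' @param fraction hold-out fraction.
#' @param seed seed for the hold-out draw.
#' @param extreme_threshold_f cutoff for the extreme subset (default 100 F,
#'   i.e. 37.78 C).
#' @param signed_errors also return per-method mean signed error
#'   (prediction minus truth) on the extreme subset.
#' @return an \code{rmspe_report}: list with \code{overall} (data frame
#'   method, rmspe_f, rmspe_extreme_f, mean_signed_error_extreme_f),
#'   \code{per_monitor} (long data frame), \code{winners} (per-monitor best
#'   method), \code{losers} (per-monitor worst method), \code{holdout}.
#' @export
compare_methods <- function(grid, methods = c("temporal", "spatial",
                                              "spatiotemporal"),
                            fraction = 0.10, seed = 1L,
                            extreme_threshold_f = 100,
                            signed_errors = TRUE) {
  imputers <- if (is.character(methods)) {
    builtin_imputers()[methods]
  } else methods
  if (!length(imputers) || any(!vapply(imputers, is.function, TRUE))) {
    stop("methods must name built-in imputers or be a named list of ",
         "functions")
  }
  ho <- draw_holdout(grid, fraction, seed)
  if (nrow(ho$cells) == 0L) {
    stop("hold-out sample is empty; increase fraction or grid size")
  }
  reduced <- mask_holdout(grid, ho)
  idx <- cbind(ho$cells$row, ho$cells$col)
  truth <- ho$cells$true_hi_f
  ext <- truth > extreme_threshold_f
  overall <- list()
  permon <- list()
  preds <- list()
  for (m in names(imputers)) {
    completed <- imputers[[m]](reduced)
    p <- completed$values[idx]
    preds[[m]] <- p
    overall[[m]] <- data.frame(
      method = m,
      rmspe_f = rmspe(p, truth),
      rmspe_extreme_f = if (any(ext)) rmspe(p, truth, extreme_threshold_f)
                        else NA_real_,
      mean_signed_error_extreme_f = if (signed_errors && any(ext)) {
        mean((p - truth)[ext])
      } else NA_real_,
      stringsAsFactors = FALSE)
    by_mon <- tapply(seq_along(truth), ho$cells$monitor_id, function(ii) {
      c(rmspe_f = rmspe(p[ii], truth[ii]),
        n = length(ii))
    })
    permon[[m]] <- data.frame(
      method = m,
      monitor_id = names(by_mon),
      rmspe_f = vapply(by_mon, `[[`, 0, "rmspe_f"),
      n = vapply(by_mon, `[[`, 0, "n"),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  per_monitor <- do.call(rbind, permon)
  wide <- stats::reshape(per_monitor[, c("method", "monitor_id", "rmspe_f")],
                         direction = "wide", idvar = "monitor_id",
                         timevar = "method")
  mcols <- sub("^rmspe_f\\.", "", names(wide)[-1L])
  best <- mcols[apply(as.matrix(wide[, -1L, drop = FALSE]), 1L, which.min)]
  worst <- mcols[apply(as.matrix(wide[, -1L, drop = FALSE]), 1L, which.max)]
  structure(list(
    overall = do.call(rbind, overall),
    per_monitor = per_monitor,
    winners = data.frame(monitor_id = wide$monitor_id, best = best,
                         worst = worst, stringsAsFactors = FALSE),
    holdout = ho,
    extreme_threshold_f = extreme_threshold_f
  ), class = "rmspe_report")
}

#' @export
print.rmspe_report <- function(x, ...) {
  cat("<rmspe_report> hold-out fraction", x$holdout$fraction, "seed",
      x$holdout$seed, "\n")
  print(x$overall, row.names = FALSE)
  tab <- table(x$winners$best)
  cat("per-monitor winners:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
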