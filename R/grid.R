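#' Heat-index grid
#'
#' The central container: a monitor-by-day matrix of daily maximum heat index
#' (degrees Fahrenheit) over a warm-season calendar. Missing monitor-days are
#' \code{NA}; the observation mask is therefore \code{!is.na(values)}.
#'
#' @param values numeric matrix, monitors in rows (rownames = monitor ids),
#'   in-season days in columns (one per calendar row). \code{NA} = missing.
#' @param calendar a \code{warm_calendar}.
#' @param network a \code{monitor_network}; row order must match
#'   \code{values}.
#' @return an object of class \code{hi_grid}.
#' @export
hi_grid <- function(values, calendar, network) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(calendar)) {
    stop("grid has ", ncol(values), " day columns but calendar has ",
         nrow(calendar), " days")
  }
  if (nrow(values) != nrow(network)) {
    stop("grid has ", nrow(values), " monitor rows but network has ",
         nrow(network), " monitors")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- network$monitor_id
  } else if (!identical(rownames(values), network$monitor_id)) {
    stop("grid rownames do not match network monitor ids")
  }
  obs <- values[!is.na(values)]
  if (length(obs) && any(!is.finite(obs))) {
    stop("observed grid values must be finite")
  }
  structure(list(values = values, calendar = calendar, network = network),
            class = "hi_grid")
}

#' @export
print.hi_grid <- function(x, ...) {
  cat(sprintf(
    "<hi_grid> %d monitors x %d days (%d-%d), %.1f%% observed\n",
    nrow(x$values), ncol(x$values),
    attr(x$calendar, "start_year"), attr(x$calendar, "end_year"),
    100 * mean(!is.na(x$values))))
  invisible(x)
}

#' Observation mask of a grid
#' @param grid an \code{hi_grid}.
#' @return logical matrix, \code{TRUE} where a value was observed.
#' @export
grid_mask <- function(grid) !is.na(grid$values)

#' Total number of monitor-day cells
#'
#' The product of monitors and in-season days, e.g. 43 monitors over the
#' 1973-2012 warm seasons give 43 x 7320 = 314,760 cells.
#'
#' @param grid an \code{hi_grid}.
#' @return integer cell count.
#' @export
grid_cell_count <- function(grid) {
  nrow(grid$values) * ncol(grid$values)
}

#' Write monitor metadata and daily records
#'
#' \code{write_network} writes \code{monitor_id,latitude,longitude,region};
#' \code{write_grid} writes observed cells only as
#' \code{monitor_id,date,hi_max_f} (missing days are simply absent). Floats
#' are written with 4 decimal places.
#'
#' @param network a \code{monitor_network}.
#' @param grid an \code{hi_grid}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_network <- function(network, path) {
  df <- data.frame(
    monitor_id = network$monitor_id,
    latitude = sprintf("%.4f", network$latitude),
    longitude = sprintf("%.4f", network$longitude),
    region = network$region,
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
write_grid <- function(grid, path) {
  idx <- which(!is.na(grid$values), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(
    monitor_id = rownames(grid$values)[idx[, 1L]],
    date = format(grid$calendar$date[idx[, 2L]], "%Y-%m-%d"),
    hi_max_f = sprintf("%.4f", grid$values[idx]),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read monitor metadata
#' @param path a monitors.csv path (columns
#'   \code{monitor_id,latitude,longitude,region}).
#' @return a \code{monitor_network}.
#' @export
read_network <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(monitor_id = "character"))
  need <- c("monitor_id", "latitude", "longitude", "region")
  if (!all(need %in% names(df))) {
    stop("monitors file must have columns ", paste(need, collapse = ","))
  }
  monitor_network(df$monitor_id, df$latitude, df$longitude, df$region)
}

#' Read daily records into a grid
#'
#' Builds an \code{hi_grid} over the given year span from a
#' \code{monitor_id,date,hi_max_f} records file and a monitors file. Cells
#' with no record are missing. Records dated outside the April-September
#' season are dropped (a count is reported via message); records for unknown
#' monitors or duplicated monitor-days are errors.
#'
#' @param records_path daily.csv path.
#' @param metadata_path monitors.csv path.
#' @param start_year,end_year year span of the calendar; if \code{NULL},
#'   inferred from the records (which must then be non-empty).
#' @return an \code{hi_grid}.
#' @export
read_grid <- function(records_path, metadata_path,
                      start_year = NULL, end_year = NULL) {
  network <- read_network(metadata_path)
  rec <- utils::read.csv(records_path, stringsAsFactors = FALSE,
                         colClasses = c(monitor_id = "character"))
  if (nrow(rec) == 0L && (is.null(start_year) || is.null(end_year))) {
    stop("records file is empty; supply start_year and end_year")
  }
  if (nrow(rec)) {
    need <- c("monitor_id", "date", "hi_max_f")
    if (!all(need %in% names(rec))) {
      stop("records file must have columns ", paste(need, collapse = ","))
    }
    rec$date <- as.Date(rec$date)
    if (anyNA(rec$date)) stop("unparseable dates in records file")
  }
  if (is.null(start_year)) start_year <- min(as.integer(format(rec$date, "%Y")))
  if (is.null(end_year)) end_year <- max(as.integer(format(rec$date, "%Y")))
  calendar <- build_calendar(start_year, end_year)
  values <- matrix(NA_real_, nrow(network), nrow(calendar),
                   dimnames = list(network$monitor_id, NULL))
  if (nrow(rec)) {
    unknown <- setdiff(unique(rec$monitor_id), network$monitor_id)
    if (length(unknown)) {
      stop("records reference unknown monitor id(s): ",
           paste(unknown, collapse = ", "))
    }
    tt <- date_to_t(calendar, rec$date)
    off <- is.na(tt)
    if (any(off)) {
      message("read_grid: dropped ", sum(off), " out-of-season record(s)")
      rec <- rec[!off, , drop = FALSE]
      tt <- tt[!off]
    }
    key <- paste(rec$monitor_id, rec$date)
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicate record for monitor-day: ", d)
    }
    values[cbind(match(rec$monitor_id, network$monitor_id), tt)] <-
      as.numeric(rec$hi_max_f)
  }
  hi_grid(values, calendar, network)
}

#' Write and read held-out truth tables
#'
#' Held-out cells are stored as \code{monitor_id,date,true_hi_f}.
#'
#' @param heldout data frame with columns \code{monitor_id}, \code{date}
#'   (Date), \code{true_hi_f}.
#' @param path file path.
#' @return the path (writer) or the data frame (reader).
#' @export
write_heldout <- function(heldout, path) {
  df <- data.frame(
    monitor_id = heldout$monitor_id,
    date = format(as.Date(heldout$date), "%Y-%m-%d"),
    true_hi_f = sprintf("%.4f", heldout$true_hi_f),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_heldout
#' @export
read_heldout <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(monitor_id = "character"))
  df$date <- as.Date(df$date)
  df$true_hi_f <- as.numeric(df$true_hi_f)
  df
}
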