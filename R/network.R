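#' Monitor network
#'
#' A set of weather monitors with coordinates and region membership, plus the
#' great-circle distance matrix used by all spatial models. Distances are
#' haversine with Earth radius 6371 km.
#'
#' @param monitor_id character vector of unique monitor ids.
#' @param latitude,longitude decimal degrees.
#' @param region region label per monitor (each monitor belongs to exactly
#'   one region, e.g. an NWS forecast region).
#' @return A \code{monitor_network}: data frame with the four columns and a
#'   \code{"distance_km"} attribute holding the symmetric pairwise
#'   great-circle distance matrix (km, zero diagonal, dimnames = ids).
#' @export
monitor_network <- function(monitor_id, latitude, longitude, region) {
  monitor_id <- as.character(monitor_id)
  region <- as.character(region)
  if (anyDuplicated(monitor_id)) {
    stop("duplicate monitor ids: ",
         paste(unique(monitor_id[duplicated(monitor_id)]), collapse = ", "))
  }
  n <- length(monitor_id)
  stopifnot(length(latitude) == n, length(longitude) == n, length(region) == n)
  if (any(!is.finite(latitude)) || any(!is.finite(longitude)) ||
      any(abs(latitude) > 90) || any(abs(longitude) > 180)) {
    stop("invalid coordinates")
  }
  net <- data.frame(
    monitor_id = monitor_id,
    latitude = as.numeric(latitude),
    longitude = as.numeric(longitude),
    region = region,
    stringsAsFactors = FALSE
  )
  attr(net, "distance_km") <- haversine_matrix(longitude, latitude, monitor_id)
  class(net) <- c("monitor_network", "data.frame")
  net
}

# Pairwise haversine distances in km, Earth radius 6371 km.
haversine_matrix <- function(lon, lat, ids = NULL) {
  p <- cbind(lon, lat)
  n <- nrow(p)
  d <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      j <- (i + 1L):n
      dij <- geosphere::distHaversine(p[i, , drop = FALSE], p[j, , drop = FALSE],
                                      r = 6371000) / 1000
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  dimnames(d) <- list(ids, ids)
  d
}

#' Distance matrix of a network
#' @param network a \code{monitor_network}.
#' @return symmetric matrix of great-circle distances in km.
#' @export
network_distances <- function(network) {
  attr(network, "distance_km")
}

#' Region labels present in a network
#' @param network a \code{monitor_network}.
#' @return character vector of unique region labels, in order of appearance.
#' @export
network_regions <- function(network) {
  unique(network$region)
}

#' Monitors belonging to one region
#' @param network a \code{monitor_network}.
#' @param region a single region label.
#' @return character vector of monitor ids.
#' @export
region_monitors <- function(network, region) {
  if (!region %in% network$region) stop("unknown region: ", region)
  network$monitor_id[network$region == region]
}
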