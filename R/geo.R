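EARTH_RADIUS_KM <- 6371.0
KM_PER_DEGREE <- 111.32

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' vectorised decimal degrees.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @examples
#' haversineKm(0, 0, 0, 1)      # ~111.19 km
#' haversineKm(0, 0, 0, 180)    # half circumference, ~20015 km
#' @export
haversineKm <- function(lat1, lon1, lat2, lon2) {
  if (!all(is.finite(c(lat1, lon1, lat2, lon2))))
    stop("haversineKm: non-finite coordinate input")
  toRad <- pi / 180
  phi1 <- lat1 * toRad; phi2 <- lat2 * toRad
  dphi <- (lat2 - lat1) * toRad
  dlam <- (lon2 - lon1) * toRad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Convert per-coordinate standard deviations (degrees) to a km radius
#'
#' Combines a latitude sd and a longitude sd into one spatial sd using the
#' local km-per-degree scale (111.32 km per degree latitude; scaled by
#' cos(latitude) for longitude).
#'
#' @param sdLat,sdLon standard deviations in degrees (>= 0).
#' @param atLat latitude (degrees) at which the conversion is evaluated.
#' @return combined spatial standard deviation in km.
#' @export
latlonSdToKm <- function(sdLat, sdLon, atLat) {
  stopifnot(all(sdLat >= 0), all(sdLon >= 0))
  sqrt((sdLat * KM_PER_DEGREE)^2 +
         (sdLon * KM_PER_DEGREE * cos(atLat * pi / 180))^2)
}

#' Build the fixed assignment grid
#'
#' Regular lattice spanning exactly the min-max latitude and longitude of the
#' training samples, with square cells of edge \code{cellKm} km. The latitude
#' step is cellKm / 111.32 degrees and the longitude step cellKm / (111.32 *
#' cos(mean training latitude)); the last cell on each axis may be truncated
#' at the max edge. Cells are half-open [low, high) except the last per axis.
#'
#' @param samples training sample table.
#' @param cellKm cell edge length in km.
#' @return a \linkS4class{GeoGrid} with memberships for the training samples.
#' @export
buildGrid <- function(samples, cellKm) {
  stopifnot(cellKm > 0)
  lat <- samples$lat; lon <- samples$lon
  if (length(unique(paste(lat, lon))) < 2L)
    stop("buildGrid: all samples at a single location")
  latStep <- cellKm / KM_PER_DEGREE
  lonStep <- cellKm / (KM_PER_DEGREE * cos(mean(lat) * pi / 180))
  latEdges <- gridEdges(min(lat), max(lat), latStep)
  lonEdges <- gridEdges(min(lon), max(lon), lonStep)
  nLat <- length(latEdges) - 1L
  nLon <- length(lonEdges) - 1L
  latBin <- rep(seq_len(nLat), times = nLon)
  lonBin <- rep(seq_len(nLon), each = nLat)
  cells <- data.frame(
    cell_id = sprintf("c%03d_%03d", latBin, lonBin),
    center_lat = (latEdges[latBin] + latEdges[latBin + 1L]) / 2,
    center_lon = (lonEdges[lonBin] + lonEdges[lonBin + 1L]) / 2,
    lat_bin = latBin, lon_bin = lonBin,
    stringsAsFactors = FALSE)
  memb <- gridCellId(latEdges, lonEdges, lat, lon)
  names(memb) <- samples$sample_id
  new("GeoGrid", cellKm = cellKm, latEdges = latEdges, lonEdges = lonEdges,
      cells = cells, membership = memb)
}

# edges from lo to hi in steps of `step`; last cell truncated at hi.
gridEdges <- function(lo, hi, step) {
  span <- hi - lo
  n <- max(1L, ceiling(span / step - 1e-9))
  e <- lo + step * seq(0L, n)
  e[length(e)] <- hi
  if (span == 0) e <- c(lo, lo + step)   # degenerate axis: one cell
  e
}

# half-open [low, high) binning, last cell closed.
gridBin <- function(edges, x) {
  b <- findInterval(x, edges, rightmost.closed = TRUE, left.open = FALSE)
  n <- length(edges) - 1L
  pmin(pmax(b, 1L), n)
}

#' Map coordinates to grid cell ids
#'
#' @param latEdges,lonEdges grid edge vectors.
#' @param lat,lon coordinates in degrees.
#' @return character vector of cell ids.
#' @keywords internal
gridCellId <- function(latEdges, lonEdges, lat, lon) {
  sprintf("c%03d_%03d", gridBin(latEdges, lat), gridBin(lonEdges, lon))
}

#' Locate samples on an existing grid
#'
#' @param grid a \linkS4class{GeoGrid}.
#' @param lat,lon coordinates in degrees.
#' @return character vector of cell ids.
#' @export
gridLocate <- function(grid, lat, lon) {
  gridCellId(grid@latEdges, grid@lonEdges, lat, lon)
}
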