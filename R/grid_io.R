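#' Regular latitude-longitude grid specification
#'
#' Describes a regular lat-lon grid by cell centres and bounds. Longitudes use
#' the \[-180, 180) convention with half-open cells; latitudes run from south
#' to north. Cell bounds tile the requested sphere segment without overlap.
#'
#' @param nlat,nlon Number of latitude / longitude cells.
#' @param lat_range Latitude extent in degrees, south first. Default
#'   `c(-60, 60)`: the synthetic world omits polar caps, where the present
#'   analysis carries no population.
#' @param lon_range Longitude extent in degrees.
#' @return An object of class `grid_spec`: list with `lat`, `lon` (centres),
#'   `lat_bounds`, `lon_bounds` (length n+1), `nlat`, `nlon`.
#' @export
grid_spec <- function(nlat, nlon, lat_range = c(-60, 60),
                      lon_range = c(-180, 180)) {
  stopifnot(nlat >= 1, nlon >= 1,
            lat_range[1] < lat_range[2], lon_range[1] < lon_range[2],
            lat_range[1] >= -90, lat_range[2] <= 90)
  lat_bounds <- seq(lat_range[1], lat_range[2], length.out = nlat + 1)
  lon_bounds <- seq(lon_range[1], lon_range[2], length.out = nlon + 1)
  g <- list(
    lat = (lat_bounds[-1] + lat_bounds[-(nlat + 1)]) / 2,
    lon = (lon_bounds[-1] + lon_bounds[-(nlon + 1)]) / 2,
    lat_bounds = lat_bounds, lon_bounds = lon_bounds,
    nlat = nlat, nlon = nlon
  )
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              x$nlat, x$nlon, min(x$lat_bounds), max(x$lat_bounds),
              min(x$lon_bounds), max(x$lon_bounds)))
  invisible(x)
}

#' Cell areas of a regular lat-lon grid
#'
#' Spherical cell areas in km^2 (Earth radius 6371 km); the area of a cell is
#' proportional to the increment of sin(latitude) across it times its
#' longitude width, so summing `density * cell_areas(grid)` gives people.
#'
#' @param grid A [grid_spec()].
#' @return Matrix `nlat x nlon` of areas (km^2).
#' @export
cell_areas <- function(grid) {
  r <- 6371
  dsin <- diff(sin(grid$lat_bounds * pi / 180))
  dlon <- diff(grid$lon_bounds) * pi / 180
  r^2 * outer(dsin, dlon)
}

# Overlap length matrix between two sets of 1-d cell bounds, in the metric
# given by transform f (identity for lon degrees, sin(lat) for areas).
.overlap_matrix <- function(dst_bounds, src_bounds, f = identity) {
  nd <- length(dst_bounds) - 1L
  ns <- length(src_bounds) - 1L
  db <- f(dst_bounds); sb <- f(src_bounds)
  lo <- pmax(matrix(db[seq_len(nd)], nd, ns),
             matrix(sb[seq_len(ns)], nd, ns, byrow = TRUE))
  hi <- pmin(matrix(db[-1L], nd, ns),
             matrix(sb[-1L], nd, ns, byrow = TRUE))
  pmax(hi - lo, 0)
}

#' First-order conservative remapping between regular lat-lon grids
#'
#' Remaps an intensive field (a density such as persons/km^2, an index value,
#' or HDI) from one regular grid to another by area-overlap weighting: each
#' target cell's value is the area-weighted mean of the source cells it
#' intersects. For density fields this conserves the area-integrated total
#' wherever the two grids cover the same domain. Missing source cells (NA)
#' are excluded from the weights; a target cell whose every contributor is
#' missing becomes NA.
#'
#' @param field Matrix `src$nlat x src$nlon`.
#' @param src,dst Source and target [grid_spec()]s.
#' @return Matrix `dst$nlat x dst$nlon`.
#' @export
remap_conservative <- function(field, src, dst) {
  stopifnot(inherits(src, "grid_spec"), inherits(dst, "grid_spec"))
  if (!all(dim(field) == c(src$nlat, src$nlon)))
    stop("field dimensions do not match source grid")
  w_lat <- .overlap_matrix(dst$lat_bounds, src$lat_bounds,
                           function(b) sin(b * pi / 180))
  w_lon <- .overlap_matrix(dst$lon_bounds, src$lon_bounds)
  if (sum(w_lat) == 0 || sum(w_lon) == 0)
    stop("source and target grids do not overlap")
  v <- field
  m <- !is.na(v)
  v[!m] <- 0
  num <- w_lat %*% v %*% t(w_lon)
  den <- w_lat %*% (m + 0) %*% t(w_lon)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Rasterize a country-index field onto a target grid
#'
#' Assigns each target cell the country occupying the largest overlap area
#' (majority-area rule); ties are broken by the lowest country id. Source
#' cells with NA country (sea / no-country sentinel) contribute no area, and
#' a target cell overlapped only by sentinel cells is NA.
#'
#' @param countries Integer matrix `src$nlat x src$nlon` of country ids
#'   (NA = no country).
#' @param src,dst Source and target [grid_spec()]s.
#' @return Integer matrix `dst$nlat x dst$nlon`.
#' @export
rasterize_countries <- function(countries, src, dst) {
  stopifnot(inherits(src, "grid_spec"), inherits(dst, "grid_spec"))
  if (!all(dim(countries) == c(src$nlat, src$nlon)))
    stop("country raster dimensions do not match source grid")
  w_lat <- .overlap_matrix(dst$lat_bounds, src$lat_bounds,
                           function(b) sin(b * pi / 180))
  w_lon <- .overlap_matrix(dst$lon_bounds, src$lon_bounds)
  ids <- sort(unique(countries[!is.na(countries)]))
  best_w <- matrix(0, dst$nlat, dst$nlon)
  best_id <- matrix(NA_integer_, dst$nlat, dst$nlon)
  for (id in ids) {          # ascending ids + strict '>' => ties keep lowest id
    w <- w_lat %*% ((!is.na(countries) & countries == id) + 0) %*% t(w_lon)
    take <- w > best_w + 1e-12 * max(w)
    best_id[take] <- id
    best_w[take] <- w[take]
  }
  best_id
}

#' Write / read a gridded field as plain-text CSV
#'
#' Long-format CSV (`lat, lon, value`) with values printed at full double
#' precision (17 significant digits), so a write-then-read round trip is
#' bit-exact, NA cells included. Row order is longitude-major over a regular
#' grid, from which [read_field_csv()] reconstructs the matrix and grid.
#'
#' @param field Matrix `grid$nlat x grid$nlon`.
#' @param grid A [grid_spec()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, grid, path) {
  stopifnot(all(dim(field) == c(grid$nlat, grid$nlon)))
  df <- data.frame(
    lat = rep(grid$lat, times = grid$nlon),
    lon = rep(grid$lon, each = grid$nlat),
    value = ifelse(is.na(as.vector(field)), "",
                   sprintf("%.17g", as.vector(field))),
    stringsAsFactors = FALSE
  )
  df$lat <- sprintf("%.17g", df$lat)
  df$lon <- sprintf("%.17g", df$lon)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @param lat_range,lon_range Grid extent, needed to rebuild cell bounds from
#'   centres on read.
#' @return For `read_field_csv`: list with `field` and `grid`.
#' @export
read_field_csv <- function(path, lat_range = c(-60, 60),
                           lon_range = c(-180, 180)) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric", "character"))
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  grid <- grid_spec(length(lat), length(lon), lat_range, lon_range)
  field <- matrix(NA_real_, grid$nlat, grid$nlon)
  i <- match(df$lat, lat)
  j <- match(df$lon, lon)
  field[cbind(i, j)] <- suppressWarnings(as.numeric(df$value))
  list(field = field, grid = grid)
}
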