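# The gridded_field container: scalar or vector fields on a regular lon/lat
# grid with daily time steps. Carrier for u, v, SST, chlorophyll, FSLE and
# SST-gradient fields. Values are stored as arrays dim = (nlon, nlat, ntime).

#' Construct a gridded field
#'
#' A regular longitude/latitude grid with one or more variables sampled at
#' daily time steps. This is the in-memory equivalent of the usual
#' CF-convention gridded file (dimensions time/lat/lon); see
#' [write_field_csv()] for the plain-text round-trip.
#'
#' @param lon,lat strictly increasing coordinate vectors (degrees).
#' @param time numeric vector of days (e.g. `as.numeric(as.Date(...))`);
#'   defaults to a single day 0.
#' @param data named list of arrays with dim `c(length(lon), length(lat),
#'   length(time))`; matrices are promoted to a single time slice.
#' @param units named character vector, one entry per variable.
#' @return an object of class `gridded_field`.
#' @export
gridded_field <- function(lon, lat, time = 0, data = list(), units = NULL) {
  stopifnot(length(lon) >= 2, length(lat) >= 2)
  if (any(diff(lon) <= 0) || any(diff(lat) <= 0)) {
    stop_cfg("gridded_field: coordinates must be strictly increasing")
  }
  dl <- diff(lon); dm <- diff(lat)
  if (max(abs(dl - dl[1])) > 1e-8 || max(abs(dm - dm[1])) > 1e-8) {
    stop_cfg("gridded_field: grid must be regular")
  }
  dims <- c(length(lon), length(lat), length(time))
  data <- lapply(data, function(a) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    if (!identical(dim(a), as.integer(dims))) {
      stop_cfg("gridded_field: variable dims must be (nlon, nlat, ntime)")
    }
    a
  })
  structure(
    list(lon = lon, lat = lat, time = as.numeric(time), data = data,
         units = units),
    class = "gridded_field"
  )
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf(
    "<gridded_field> %d x %d x %d (lon x lat x time)\n  lon [%g, %g], lat [%g, %g], vars: %s\n",
    length(x$lon), length(x$lat), length(x$time),
    min(x$lon), max(x$lon), min(x$lat), max(x$lat),
    paste(names(x$data), collapse = ", ")
  ))
  invisible(x)
}

#' Sample a gridded field from analytic functions
#'
#' Convenience constructor used for analytic test flows (solid-body rotation,
#' pure strain) and for building scalar fields from closed forms. Each
#' function receives vectors `lon`, `lat`, `time` (already expanded).
#'
#' @param lon,lat,time grid coordinates as in [gridded_field()].
#' @param ... named functions `f(lon, lat, time)` returning values.
#' @return a `gridded_field`.
#' @export
field_from_function <- function(lon, lat, time = 0, ...) {
  fns <- list(...)
  grid <- expand.grid(lon = lon, lat = lat, time = time)
  data <- lapply(fns, function(f) {
    array(f(grid$lon, grid$lat, grid$time),
          dim = c(length(lon), length(lat), length(time)))
  })
  gridded_field(lon, lat, time, data)
}

field_bbox <- function(field) {
  c(lon_min = min(field$lon), lon_max = max(field$lon),
    lat_min = min(field$lat), lat_max = max(field$lat))
}

in_domain <- function(field, lon, lat) {
  bb <- field_bbox(field)
  lon >= bb["lon_min"] & lon <= bb["lon_max"] &
    lat >= bb["lat_min"] & lat <= bb["lat_max"]
}

# Fractional index of `x` on the regular coordinate vector `coord`, clamped
# to the grid so that evaluation slightly outside the domain (intermediate
# Runge-Kutta stages of particles about to be flagged) degrades gracefully
# to edge values.
frac_index <- function(coord, x) {
  step <- coord[2] - coord[1]
  f <- (x - coord[1]) / step + 1
  pmin(pmax(f, 1), length(coord))
}

#' Interpolate a field variable at scattered points
#'
#' Bilinear in space, linear in time; time is clamped to the available range
#' (synthetic fields are quasi-stationary, so requests outside the stored
#' window reuse the nearest snapshot).
#'
#' @param field a `gridded_field`.
#' @param var variable name.
#' @param lon,lat,time point coordinates (vectorised; `time` recycled).
#' @return numeric vector of interpolated values.
#' @export
interp_field <- function(field, var, lon, lat, time = field$time[1]) {
  a <- field$data[[var]]
  if (is.null(a)) stop_cfg("interp_field: no variable '", var, "'")
  n <- max(length(lon), length(lat), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); time <- rep_len(time, n)

  fi <- frac_index(field$lon, lon)
  fj <- frac_index(field$lat, lat)
  i0 <- pmin(floor(fi), length(field$lon) - 1L); wx <- fi - i0
  j0 <- pmin(floor(fj), length(field$lat) - 1L); wy <- fj - j0

  nt <- length(field$time)
  if (nt == 1L) {
    k0 <- rep_len(1L, n); wt <- rep_len(0, n); k1 <- k0
  } else {
    fk <- frac_index(field$time, time)
    k0 <- pmin(floor(fk), nt - 1L); wt <- fk - k0
    k1 <- k0 + 1L
  }

  nx <- length(field$lon); ny <- length(field$lat)
  idx <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  bil <- function(k) {
    v00 <- a[idx(i0,      j0,      k)]
    v10 <- a[idx(i0 + 1L, j0,      k)]
    v01 <- a[idx(i0,      j0 + 1L, k)]
    v11 <- a[idx(i0 + 1L, j0 + 1L, k)]
    (1 - wx) * (1 - wy) * v00 + wx * (1 - wy) * v10 +
      (1 - wx) * wy * v01 + wx * wy * v11
  }
  if (nt == 1L) bil(k0) else (1 - wt) * bil(k0) + wt * bil(k1)
}

#' Write/read a gridded field as plain-text CSV (long format)
#'
#' One row per (time, lat, lon) cell with one column per variable; a
#' lossless, text-only stand-in for the usual NetCDF layout.
#'
#' @param field a `gridded_field`.
#' @param path file path.
#' @rdname field_csv
#' @export
write_field_csv <- function(field, path) {
  grid <- expand.grid(lon = field$lon, lat = field$lat, time = field$time)
  for (v in names(field$data)) grid[[v]] <- as.vector(field$data[[v]])
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname field_csv
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  time <- sort(unique(df$time))
  ord <- order(df$time, df$lat, df$lon)
  vars <- setdiff(names(df), c("lon", "lat", "time"))
  data <- lapply(df[ord, vars, drop = FALSE], function(col) {
    array(col, dim = c(length(lon), length(lat), length(time)))
  })
  gridded_field(lon, lat, time, data)
}
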