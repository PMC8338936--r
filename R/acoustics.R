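# Acoustic transect processing: layer-averaged fish concentration, 1.1-km
# acoustic units, solar day/night classification, polygon region masks.

LAYER_COLS <- sprintf("layer_%02d", 1:30)

#' Acoustic Fish Concentration of an echo profile
#'
#' The AFC of an acoustic unit is the arithmetic mean of the bifrequency
#' backscatter of 29 of its 30 depth layers (10-m bins from 10 to 300 m):
#' layer 1 (0-10 m) is excluded because of surface noise. Dimensionless.
#'
#' @param profile numeric vector of 30 layer values, a 30-column matrix
#'   (rows = acoustic units), or a data frame with columns
#'   `layer_01`..`layer_30`.
#' @return AFC value(s).
#' @export
compute_afc <- function(profile) {
  if (is.data.frame(profile)) {
    miss <- setdiff(LAYER_COLS, names(profile))
    if (length(miss)) {
      stop_cfg("compute_afc: profile lacks layers: ",
               paste(miss, collapse = ", "))
    }
    profile <- as.matrix(profile[, LAYER_COLS])
  }
  if (is.null(dim(profile))) profile <- matrix(profile, nrow = 1)
  if (ncol(profile) != 30) {
    stop_cfg("compute_afc: profile has ", ncol(profile),
             " layers; exactly 30 required")
  }
  if (any(profile < 0, na.rm = TRUE)) {
    stop_cfg("compute_afc: backscatter values must be >= 0")
  }
  rowMeans(profile[, 2:30, drop = FALSE])
}

#' Bin raw pings into acoustic units by along-track distance
#'
#' Consecutive pings are grouped while their along-track distance from the
#' first ping of the current group stays below `spacing_km`; each group is
#' averaged layerwise and positioned at its mean coordinates/time. Pings
#' already at least `spacing_km` apart pass through unchanged.
#'
#' @param pings data frame with `lon`, `lat`, `time` (sortable) and
#'   `layer_01`..`layer_30`, ordered in time.
#' @param spacing_km along-track unit spacing (default 1.1 km).
#' @return data frame of acoustic units with the same columns.
#' @export
bin_acoustic_units <- function(pings, spacing_km = 1.1) {
  if (is.unsorted(pings$time)) {
    stop_cfg("bin_acoustic_units: pings must be ordered in time")
  }
  n <- nrow(pings)
  seg <- c(0, dist_km(pings$lon[-n], pings$lat[-n],
                      pings$lon[-1], pings$lat[-1]))
  along <- cumsum(seg)
  group <- integer(n)
  g <- 1L; start <- along[1]
  for (i in seq_len(n)) {
    if (along[i] - start >= spacing_km) {
      g <- g + 1L
      start <- along[i]
    }
    group[i] <- g
  }
  agg <- function(x) as.numeric(tapply(x, group, mean))
  out <- data.frame(lon = agg(pings$lon), lat = agg(pings$lat))
  tm <- agg(as.numeric(pings$time))
  out$time <- if (inherits(pings$time, "POSIXct")) {
    as.POSIXct(tm, origin = "1970-01-01", tz = "UTC")
  } else tm
  for (cl in LAYER_COLS) out[[cl]] <- agg(pings[[cl]])
  rownames(out) <- NULL
  out
}

#' Solar elevation angle (degrees)
#'
#' NOAA-style low-precision solar position: fractional-year expansion of the
#' solar declination and the equation of time, then the hour-angle formula
#' for the elevation. Accurate to a fraction of a degree, ample for a
#' day/night split.
#'
#' @param time `POSIXct` (UTC) times.
#' @param lon,lat coordinates in degrees.
#' @return solar elevation above the horizon, degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  time <- as.POSIXlt(time, tz = "UTC")
  doy <- time$yday
  hour <- time$hour + time$min / 60 + time$sec / 3600
  g <- 2 * pi / 365 * (doy + (hour - 12) / 24)  # fractional year (rad)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  tst <- hour * 60 + eqtime + 4 * lon            # true solar time (min)
  ha <- deg2rad(tst / 4 - 180)                   # hour angle (rad)
  latr <- deg2rad(lat)
  cosz <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  90 - 180 / pi * acos(pmin(pmax(cosz, -1), 1))
}

#' Classify transect times as day or night
#'
#' Night is defined as solar elevation below 0 degrees at the point's
#' position and (UTC) time; daytime records are dropped before the front
#' statistics because diel vertical migration takes the fish below the
#' echo-sounder range during the day.
#'
#' @inheritParams solar_elevation
#' @return character vector, `"day"` or `"night"`.
#' @export
classify_daynight <- function(time, lon, lat) {
  ifelse(solar_elevation(time, lon, lat) < 0, "night", "day")
}

# cross product sign of (b-a) x (p-a)
.cross <- function(ax, ay, bx, by, px, py) {
  (bx - ax) * (py - ay) - (by - ay) * (px - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py, eps = 1e-12) {
  cr <- .cross(ax, ay, bx, by, px, py)
  abs(cr) <= eps &
    px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
    py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
}

polygon_self_intersects <- function(px, py) {
  n <- length(px)
  nxt <- c(2:n, 1)
  segs <- cbind(px, py, px[nxt], py[nxt])
  inter <- function(s1, s2) {
    d1 <- .cross(s2[1], s2[2], s2[3], s2[4], s1[1], s1[2])
    d2 <- .cross(s2[1], s2[2], s2[3], s2[4], s1[3], s1[4])
    d3 <- .cross(s1[1], s1[2], s1[3], s1[4], s2[1], s2[2])
    d4 <- .cross(s1[1], s1[2], s1[3], s1[4], s2[3], s2[4])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (inter(segs[i, ], segs[j, ])) return(TRUE)
    }
  }
  FALSE
}

#' Keep transect points strictly inside a polygon mask
#'
#' Even-odd ray casting with a strict-interior convention: points on an edge
#' or vertex are excluded. Polygons crossing the dateline are handled by
#' shifting longitudes to a contiguous 0-360 frame when the raw longitude
#' span exceeds 180 degrees. Self-intersecting polygons are rejected.
#'
#' @param points data frame with `lon`, `lat`.
#' @param polygon data frame with `lon`, `lat` vertices (closed implicitly).
#' @return the subset of `points` strictly inside the polygon.
#' @export
region_filter <- function(points, polygon) {
  keep <- in_polygon(points$lon, points$lat, polygon)
  points[keep, , drop = FALSE]
}

#' @rdname region_filter
#' @param lon,lat point coordinates.
#' @return for `in_polygon`: logical vector.
#' @export
in_polygon <- function(lon, lat, polygon) {
  px <- polygon$lon; py <- polygon$lat
  if (length(px) < 3) stop_cfg("in_polygon: polygon needs >= 3 vertices")
  if (max(px) - min(px) > 180) {
    px <- ifelse(px < 0, px + 360, px)
    lon <- ifelse(lon < 0, lon + 360, lon)
  }
  if (polygon_self_intersects(px, py)) {
    stop_cfg("in_polygon: polygon is self-intersecting")
  }
  n <- length(px)
  nxt <- c(2:n, 1)
  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]
    if (any(.on_segment(px, py, px[nxt], py[nxt], x, y))) return(FALSE)
    inside <- FALSE
    for (i in seq_len(n)) {
      j <- nxt[i]
      if ((py[i] > y) != (py[j] > y)) {
        xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}
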