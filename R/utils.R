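# Shared helpers: geometry on the equirectangular plane, seeded RNG scopes.

# Kilometres per degree of latitude (and of longitude at the equator).
KM_PER_DEG <- 111.32

deg2rad <- function(x) x * pi / 180

#' Equirectangular distance between points, in kilometres
#'
#' Zonal separations are scaled by the cosine of the mean latitude of each
#' pair. Adequate for the sub-degree separations used throughout (FSLE
#' particle pairs, along-track spacing, colocation discs).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees (vectorised).
#' @return distance in km.
#' @keywords internal
dist_km <- function(lon1, lat1, lon2, lat2) {
  latm <- deg2rad((lat1 + lat2) / 2)
  dx <- (lon2 - lon1) * cos(latm) * KM_PER_DEG
  dy <- (lat2 - lat1) * KM_PER_DEG
  sqrt(dx^2 + dy^2)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_cfg <- function(...) stop(..., call. = FALSE)
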