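# Colocation of gridded diagnostics along a ship track.

#' Colocation parameters
#'
#' @param sigma neighbourhood radius in degrees (default 0.2, the reference
#'   configuration; the disc lives in degree space with zonal offsets scaled
#'   by cos(lat)).
#' @export
colocation_params <- function(sigma = 0.2) {
  if (sigma <= 0) stop_cfg("colocation_params: sigma must be > 0")
  structure(list(sigma = sigma), class = "colocation_params")
}

#' Colocate a gridded variable at track points
#'
#' Returns, for each point, the mean of the grid-cell values whose centres
#' lie within radius `sigma` (degrees; zonal separation scaled by the cosine
#' of the point latitude) at the matching day (nearest stored time). Points
#' with no qualifying cell get `NA`.
#'
#' @param field `gridded_field`.
#' @param var variable name.
#' @param lon,lat,time point coordinates (time in days on the field axis;
#'   recycled).
#' @param params a [colocation_params()] object.
#' @return numeric vector (NA where no cell qualifies).
#' @export
colocate <- function(field, var, lon, lat, time = field$time[1],
                     params = colocation_params()) {
  a <- field$data[[var]]
  if (is.null(a)) stop_cfg("colocate: no variable '", var, "'")
  n <- max(length(lon), length(lat), length(time))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n); time <- rep_len(time, n)
  sigma <- params$sigma
  glon <- field$lon; glat <- field$lat
  nt <- length(field$time)
  kk <- if (nt == 1L) rep_len(1L, n) else {
    vapply(time, function(t) which.min(abs(field$time - t)), integer(1))
  }
  out <- rep(NA_real_, n)
  for (p in seq_len(n)) {
    cl <- cos(deg2rad(lat[p]))
    i <- which(abs(glon - lon[p]) * cl <= sigma)
    j <- which(abs(glat - lat[p]) <= sigma)
    if (!length(i) || !length(j)) next
    dx <- (glon[i] - lon[p]) * cl
    dy <- glat[j] - lat[p]
    d2 <- outer(dx^2, dy^2, "+")
    vals <- a[i, j, kk[p], drop = FALSE]
    sel <- d2 <= sigma^2
    if (any(sel)) out[p] <- mean(vals[sel])
  }
  out
}
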