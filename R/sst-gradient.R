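# Kilometric SST gradient on a regular lon/lat grid.

#' Compute the sea-surface-temperature gradient norm (degC/km)
#'
#' Central differences over neighbouring cells:
#' `g_x = (SST[i+1] - SST[i-1]) / (2 dx)` with `dx` the kilometric
#' longitudinal spacing (varies with latitude as `cos(lat)`), and likewise
#' `g_y` with the kilometric latitudinal spacing (about 5.6 km for a 0.05
#' degree grid). Boundary cells use one-sided differences. The gradient norm
#' is `sqrt(g_x^2 + g_y^2)`.
#'
#' @param sst `gridded_field` with variable `sst` (degC).
#' @param var variable name (default `"sst"`).
#' @return `gridded_field` with variables `grad` (norm, degC/km), `gx`, `gy`.
#' @export
compute_sst_gradient <- function(sst, var = "sst") {
  a <- sst$data[[var]]
  if (is.null(a)) stop_cfg("compute_sst_gradient: no variable '", var, "'")
  nx <- length(sst$lon); ny <- length(sst$lat); nt <- length(sst$time)
  if (nx < 3 || ny < 3) {
    stop_cfg("compute_sst_gradient: need at least 3 cells per axis")
  }
  dlon <- sst$lon[2] - sst$lon[1]
  dlat <- sst$lat[2] - sst$lat[1]
  dx_km <- dlon * KM_PER_DEG * cos(deg2rad(sst$lat))  # per-latitude row
  dy_km <- dlat * KM_PER_DEG

  # centred differences with one-sided boundaries along dimension 1 (lon)
  diff_centred <- function(m, d) {
    out <- m
    n <- nrow(m)
    out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * d)
    out[1, ] <- (m[2, ] - m[1, ]) / d
    out[n, ] <- (m[n, ] - m[n - 1, ]) / d
    out
  }

  gx <- array(0, dim = dim(a)); gy <- gx
  for (k in seq_len(nt)) {
    sl <- a[, , k]
    gxk <- diff_centred(sl, 1)                 # per unit lon index
    gxk <- sweep(gxk, 2, dx_km, "/")           # divide by km spacing at lat j
    gyk <- t(diff_centred(t(sl), dy_km))
    gx[, , k] <- gxk
    gy[, , k] <- gyk
  }
  gridded_field(sst$lon, sst$lat, sst$time,
                data = list(grad = sqrt(gx^2 + gy^2), gx = gx, gy = gy),
                units = c(grad = "degC/km", gx = "degC/km", gy = "degC/km"))
}
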