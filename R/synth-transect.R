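# Synthetic ship transects: acoustic units with a limiting-factor AFC law
# and per-unit 30-layer echo profiles.

#' Specification of a synthetic acoustic transect
#'
#' Acoustic units are laid every `spacing_km` along the waypoint polyline and
#' time-stamped from the ship speed. The latent Acoustic Fish Concentration
#' follows a limiting-factor law:
#'
#' `AFC_i = B_i + U_i * slope * diag_i * 1[chl_i > chl_gate]`
#'
#' with `U_i ~ Uniform(0, 1)` and `B_i = baseline * (1 + baseline_noise *
#' (2 W_i - 1))`, `W_i ~ Uniform(0, 1)`. With the default `baseline_noise = 0`
#' the baseline is the constant `baseline` and the conditional tau-quantile of
#' AFC given the diagnostic is exactly linear: front intensity bounds, but
#' does not determine, the fish concentration. A positive `baseline_noise`
#' adds the order-one background variability of real backscatter (unobserved
#' factors), needed for any meaningful null-hypothesis world.
#'
#' @param waypoints data frame with `lon`, `lat` (at least 2 rows).
#' @param spacing_km along-track unit spacing (default 1.1 km).
#' @param start_time `POSIXct` (UTC) departure time.
#' @param speed_kmh ship speed (default 18.5 km/h, about 10 knots).
#' @param baseline baseline AFC (dimensionless, > 0).
#' @param slope front-effect slope (AFC per diagnostic unit, >= 0).
#' @param chl_gate chlorophyll gate threshold (mg/m^3); the front effect is
#'   active only in chlorophyll-rich water. `0` disables the gate.
#' @param baseline_noise half-width of the uniform baseline multiplier
#'   (default 0: the exact limiting-factor law).
#' @param surface_noise_scale additive positive noise on layer 1, in units of
#'   `baseline` (default 10: surface noise an order of magnitude above the
#'   deep-layer scale, making the 29-of-30 exclusion rule consequential).
#' @param seed RNG seed; identical seed gives an identical transect.
#' @export
transect_spec <- function(waypoints, spacing_km = 1.1,
                          start_time = as.POSIXct("2014-06-20 12:00:00",
                                                  tz = "UTC"),
                          speed_kmh = 18.5, baseline = 1, slope = 3,
                          chl_gate = 0.22, baseline_noise = 0,
                          surface_noise_scale = 10, seed = 1) {
  if (spacing_km <= 0) stop_cfg("transect_spec: spacing_km must be > 0")
  if (slope < 0) stop_cfg("transect_spec: slope must be >= 0")
  if (nrow(waypoints) < 2) stop_cfg("transect_spec: need >= 2 waypoints")
  structure(list(waypoints = waypoints, spacing_km = spacing_km,
                 start_time = start_time, speed_kmh = speed_kmh,
                 baseline = baseline, slope = slope, chl_gate = chl_gate,
                 baseline_noise = baseline_noise,
                 surface_noise_scale = surface_noise_scale, seed = seed),
            class = "transect_spec")
}

# positions every spacing_km along the waypoint polyline
densify_track <- function(waypoints, spacing_km) {
  n <- nrow(waypoints)
  seg <- dist_km(waypoints$lon[-n], waypoints$lat[-n],
                 waypoints$lon[-1], waypoints$lat[-1])
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[n], by = spacing_km)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  f <- (s - cum[i]) / seg[i]
  data.frame(
    lon = waypoints$lon[i] + f * (waypoints$lon[i + 1] - waypoints$lon[i]),
    lat = waypoints$lat[i] + f * (waypoints$lat[i + 1] - waypoints$lat[i]),
    dist_km = s
  )
}

# deterministic depth shape for layers 2..30 (10-m bins, 10-300 m), peaked
# around 100 m and normalised to mean 1 so the layer mean reproduces AFC
# exactly
.depth_shape <- local({
  depth <- seq(15, 295, by = 10)  # centres of layers 2..30
  s <- exp(-((depth - 100) / 120)^2)
  s / mean(s)
})

#' Generate a synthetic acoustic transect
#'
#' Lays acoustic units along the waypoints, colocates the front diagnostic
#' (FSLE), SST gradient and chlorophyll at each unit, draws the latent AFC
#' from the limiting-factor law of [transect_spec()], and builds a 30-layer
#' echo profile per unit whose layers 2-30 average exactly to the latent AFC
#' and whose layer 1 carries strong additive surface noise. Day/night flags
#' come from the solar elevation at the unit's time and position.
#'
#' @param spec a [transect_spec()].
#' @param fsle `gridded_field` with variable `fsle` (the front diagnostic).
#' @param sst_grad `gridded_field` with variable `grad` (degC/km), or `NULL`.
#' @param chl `gridded_field` with variable `chl` (mg/m^3).
#' @param coloc a [colocation_params()] object.
#' @return data frame with one row per acoustic unit: `lon`, `lat`, `time`,
#'   `dist_km`, colocated `fsle`, `sst_grad`, `chl`, the truth columns
#'   `chl_rich` and `true_afc`, `daynight`, and `layer_01`..`layer_30`.
#' @export
gen_transect <- function(spec, fsle, sst_grad = NULL, chl,
                         coloc = colocation_params()) {
  stopifnot(inherits(spec, "transect_spec"))
  wp <- spec$waypoints
  ok <- in_domain(fsle, wp$lon, wp$lat)
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop_cfg(sprintf(
      "gen_transect: waypoint %d (lon %.3f, lat %.3f) is outside the field domain",
      bad, wp$lon[bad], wp$lat[bad]))
  }
  pts <- densify_track(wp, spec$spacing_km)
  n <- nrow(pts)
  pts$time <- spec$start_time + pts$dist_km / spec$speed_kmh * 3600
  tday <- fsle$time[1] + (as.numeric(pts$time) -
                            as.numeric(spec$start_time)) / 86400

  pts$fsle <- colocate(fsle, "fsle", pts$lon, pts$lat, tday, coloc)
  pts$sst_grad <- if (!is.null(sst_grad)) {
    colocate(sst_grad, "grad", pts$lon, pts$lat, tday, coloc)
  } else NA_real_
  pts$chl <- colocate(chl, "chl", pts$lon, pts$lat, tday, coloc)
  pts$chl_rich <- spec$chl_gate <= 0 | pts$chl > spec$chl_gate

  draws <- with_seed(spec$seed, {
    list(U = stats::runif(n), W = stats::runif(n), S = stats::runif(n))
  })
  B <- spec$baseline * (1 + spec$baseline_noise * (2 * draws$W - 1))
  pts$true_afc <- B + draws$U * spec$slope * pts$fsle * pts$chl_rich
  pts$daynight <- classify_daynight(pts$time, pts$lon, pts$lat)

  layers <- outer(pts$true_afc, .depth_shape)           # layers 2..30
  layer1 <- pts$true_afc +
    spec$surface_noise_scale * spec$baseline * draws$S  # surface noise
  prof <- cbind(layer1, layers)
  colnames(prof) <- LAYER_COLS
  cbind(pts, as.data.frame(prof))
}

#' Write/read a transect as CSV with ISO-8601 times
#'
#' @param transect data frame from [gen_transect()] (or the same layout).
#' @param path file path.
#' @rdname transect_csv
#' @export
write_transect_csv <- function(transect, path) {
  out <- transect
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname transect_csv
#' @export
read_transect_csv <- function(path) {
  df <- utils::read.csv(path)
  df$time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df
}
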