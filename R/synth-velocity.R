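# Synthetic mesoscale ocean: divergence-free eddy velocity fields and
# passively stirred SST / chlorophyll fields with known generative structure.

#' Specification of a synthetic eddy velocity field
#'
#' The stream function is a sum of Gaussian eddies (plus an optional
#' meandering zonal jet), built in the equirectangular tangent plane at the
#' domain-centre latitude. Velocities are obtained by central differences of
#' the stream function on a ghost-extended grid, so the discrete
#' central-difference divergence vanishes to machine precision.
#'
#' @param lon_range,lat_range domain bounds (degrees).
#' @param spacing grid spacing (degrees, > 0).
#' @param n_eddies number of eddies (>= 0).
#' @param amplitude_range stream-function amplitude range (m^2/s); each eddy
#'   draws a magnitude in this range and a random rotation sign. The default
#'   eddy population gives peak speeds around 0.5-0.8 m/s and
#'   finite-size-Lyapunov ridges well above the 0.08/day front threshold —
#'   an energetic mesoscale field typical of the Antarctic Circumpolar
#'   Current region the generator emulates.
#' @param radius_range eddy radius range (km, > 0).
#' @param jet optional list `(amplitude, width_km, meander_km, wavelength_km)`
#'   describing a meandering zonal jet; `NULL` (default) for none.
#' @param drift_kmday eddy-centre drift speed (km/day, default 0: the
#'   synthetic ocean is quasi-stationary, like daily altimetry relative to a
#'   ship transect).
#' @param seed RNG seed; the same seed gives a bit-identical field.
#' @export
eddy_field_spec <- function(lon_range = c(30, 54), lat_range = c(-56, -44),
                            spacing = 0.1, n_eddies = 30,
                            amplitude_range = c(10000, 30000),
                            radius_range = c(35, 75),
                            jet = NULL, drift_kmday = 0, seed = 1) {
  if (spacing <= 0) stop_cfg("eddy_field_spec: spacing must be > 0")
  if (diff(lon_range) <= 0 || diff(lat_range) <= 0) {
    stop_cfg("eddy_field_spec: empty domain")
  }
  if (n_eddies < 0) stop_cfg("eddy_field_spec: n_eddies must be >= 0")
  if (any(radius_range <= 0)) stop_cfg("eddy_field_spec: radii must be > 0")
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 spacing = spacing, n_eddies = n_eddies,
                 amplitude_range = amplitude_range,
                 radius_range = radius_range, jet = jet,
                 drift_kmday = drift_kmday, seed = seed),
            class = "eddy_field_spec")
}

# km coordinates of lon/lat in the tangent plane at the domain centre
plane_km <- function(spec, lon, lat) {
  lon0 <- mean(spec$lon_range); lat0 <- mean(spec$lat_range)
  list(x = (lon - lon0) * KM_PER_DEG * cos(deg2rad(lat0)),
       y = (lat - lat0) * KM_PER_DEG)
}

#' Generate a divergence-free synthetic velocity field
#'
#' Draws eddy centres, radii and amplitudes under the spec's seed, samples
#' the stream function psi (m^2/s) on the grid extended by one ghost cell,
#' and sets `u = -dpsi/dy`, `v = dpsi/dx` by central differences (distances
#' in metres, so u and v are in m/s). Daily snapshots; eddy centres drift at
#' `drift_kmday` in random directions.
#'
#' @param spec an [eddy_field_spec()].
#' @param n_days number of daily snapshots (default 1).
#' @return `gridded_field` with variables `u`, `v` (m/s).
#' @export
gen_velocity_field <- function(spec, n_days = 1) {
  stopifnot(inherits(spec, "eddy_field_spec"))
  lon <- seq(spec$lon_range[1], spec$lon_range[2], by = spec$spacing)
  lat <- seq(spec$lat_range[1], spec$lat_range[2], by = spec$spacing)
  eddies <- with_seed(spec$seed, {
    k <- spec$n_eddies
    th <- stats::runif(k, 0, 2 * pi)
    data.frame(
      lon = stats::runif(k, spec$lon_range[1], spec$lon_range[2]),
      lat = stats::runif(k, spec$lat_range[1], spec$lat_range[2]),
      A = stats::runif(k, spec$amplitude_range[1], spec$amplitude_range[2]) *
        sample(c(-1, 1), k, replace = TRUE),
      R = stats::runif(k, spec$radius_range[1], spec$radius_range[2]),
      ux = cos(th), uy = sin(th)
    )
  })

  # stream function (m^2/s) at plane coordinates (km) on day t
  psi_fun <- function(xk, yk, t) {
    val <- numeric(length(xk))
    if (nrow(eddies) > 0) {
      ec <- plane_km(spec, eddies$lon, eddies$lat)
      for (e in seq_len(nrow(eddies))) {
        cx <- ec$x[e] + spec$drift_kmday * t * eddies$ux[e]
        cy <- ec$y[e] + spec$drift_kmday * t * eddies$uy[e]
        r2 <- (xk - cx)^2 + (yk - cy)^2
        val <- val + eddies$A[e] * exp(-r2 / (2 * eddies$R[e]^2))
      }
    }
    if (!is.null(spec$jet)) {
      j <- spec$jet
      val <- val + j$amplitude * j$width_km *
        tanh((yk - j$meander_km * sin(2 * pi * xk / j$wavelength_km)) /
               j$width_km)
    }
    val
  }

  lat0 <- mean(spec$lat_range)
  dxe <- spec$spacing * KM_PER_DEG * cos(deg2rad(lat0))  # km
  dye <- spec$spacing * KM_PER_DEG
  # ghost-extended plane coordinates
  loe <- c(lon[1] - spec$spacing, lon, lon[length(lon)] + spec$spacing)
  lae <- c(lat[1] - spec$spacing, lat, lat[length(lat)] + spec$spacing)
  pe <- plane_km(spec, rep(loe, length(lae)), rep(lae, each = length(loe)))

  nx <- length(lon); ny <- length(lat)
  u <- array(0, dim = c(nx, ny, n_days)); v <- u
  for (t in seq_len(n_days) - 1L) {
    psi <- matrix(psi_fun(pe$x, pe$y, t), nrow = nx + 2L)
    iu <- 2:(nx + 1); ju <- 2:(ny + 1)
    u[, , t + 1L] <- -(psi[iu, ju + 1] - psi[iu, ju - 1]) / (2 * dye * 1000)
    v[, , t + 1L] <- (psi[iu + 1, ju] - psi[iu - 1, ju]) / (2 * dxe * 1000)
  }
  gridded_field(lon, lat, time = seq_len(n_days) - 1,
                data = list(u = u, v = v), units = c(u = "m/s", v = "m/s"))
}

#' Generate stirred SST and chlorophyll fields
#'
#' SST starts as a smooth meridional ramp and chlorophyll as a set of smooth
#' Gaussian patches over a background; both are advected passively
#' (semi-Lagrangian: backward trajectories from each grid node sample the
#' initial field) for `advect_days`, which wraps the tracers around eddies
#' and creates front-aligned gradients.
#'
#' @param vel `gridded_field` with `u`, `v`.
#' @param spec the [eddy_field_spec()] used to build `vel` (provides domain,
#'   plane mapping and the seed for patch placement).
#' @param advect_days stirring horizon (days, > 0).
#' @param sst_base SST at the domain centre (degC).
#' @param sst_ramp meridional ramp slope (degC/km northward, default 0.0045:
#'   a few degC across a Southern Ocean domain).
#' @param chl_background background chlorophyll (mg/m^3).
#' @param n_patches,patch_amplitude_range,patch_radius_km_range chlorophyll
#'   patch parameters; defaults give a chlorophyll-rich fraction of roughly
#'   0.4 at the 0.22 mg/m^3 threshold.
#' @param step_hours trajectory integrator step.
#' @return list with `sst` and `chl` gridded fields (time axis copied from
#'   `vel`).
#' @export
gen_scalar_fields <- function(vel, spec, advect_days = 30,
                              sst_base = 7, sst_ramp = 0.0045,
                              chl_background = 0.08,
                              n_patches = 14,
                              patch_amplitude_range = c(0.15, 0.45),
                              patch_radius_km_range = c(80, 200),
                              step_hours = 6) {
  if (advect_days <= 0) stop_cfg("gen_scalar_fields: advect_days must be > 0")
  patches <- with_seed(spec$seed + 1L, {
    k <- n_patches
    data.frame(
      lon = stats::runif(k, spec$lon_range[1], spec$lon_range[2]),
      lat = stats::runif(k, spec$lat_range[1], spec$lat_range[2]),
      A = stats::runif(k, patch_amplitude_range[1], patch_amplitude_range[2]),
      R = stats::runif(k, patch_radius_km_range[1], patch_radius_km_range[2])
    )
  })
  sst0 <- function(lon, lat) {
    p <- plane_km(spec, lon, lat)
    sst_base + sst_ramp * p$y
  }
  chl0 <- function(lon, lat) {
    p <- plane_km(spec, lon, lat)
    val <- rep(chl_background, length(lon))
    pc <- plane_km(spec, patches$lon, patches$lat)
    for (e in seq_len(nrow(patches))) {
      r2 <- (p$x - pc$x[e])^2 + (p$y - pc$y[e])^2
      val <- val + patches$A[e] * exp(-r2 / (2 * patches$R[e]^2))
    }
    val
  }

  nodes <- expand.grid(lon = vel$lon, lat = vel$lat)
  nx <- length(vel$lon); ny <- length(vel$lat); nt <- length(vel$time)
  sst <- array(0, dim = c(nx, ny, nt)); chl <- sst
  for (k in seq_len(nt)) {
    org <- advect(vel, nodes$lon, nodes$lat, t_start = vel$time[k],
                  duration_days = -advect_days, step_hours = step_hours)
    sst[, , k] <- sst0(org$lon, org$lat)
    chl[, , k] <- chl0(org$lon, org$lat)
  }
  list(
    sst = gridded_field(vel$lon, vel$lat, vel$time, list(sst = sst),
                        units = c(sst = "degC")),
    chl = gridded_field(vel$lon, vel$lat, vel$time, list(chl = chl),
                        units = c(chl = "mg/m3"))
  )
}
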