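# Lagrangian particle advection in a gridded velocity field.

#' Advect particles with a 4th-order Runge-Kutta scheme
#'
#' Integrates particle trajectories through a gridded velocity field
#' (variables `u`, `v` in m/s on a lon/lat grid). Velocity is interpolated
#' bilinearly in space and linearly in time; zonal displacement is divided by
#' `cos(lat)` when expressed in degrees. A negative `duration_days` integrates
#' backward in time. Particles that leave the domain are frozen at their last
#' in-domain position and flagged; no error is raised.
#'
#' @param vel `gridded_field` with variables `u` and `v` (m/s).
#' @param lon,lat starting positions (degrees).
#' @param t_start start time (days, on the field's time axis).
#' @param duration_days signed duration; negative means backward in time.
#' @param step_hours integrator step (default 6 h).
#' @return list with final `lon`, `lat` and logical `flagged`.
#' @export
advect <- function(vel, lon, lat, t_start = vel$time[1], duration_days,
                   step_hours = 6) {
  if (step_hours <= 0) stop_cfg("advect: step_hours must be > 0")
  if (!all(in_domain(vel, lon, lat))) {
    stop_cfg("advect: starting positions must lie inside the velocity domain")
  }
  n <- length(lon)
  stopifnot(length(lat) == n)
  flagged <- rep(FALSE, n)
  total_h <- abs(duration_days) * 24
  if (total_h == 0) return(list(lon = lon, lat = lat, flagged = flagged))
  sgn <- sign(duration_days)
  nstep <- ceiling(total_h / step_hours - 1e-9)

  # velocity in degrees/hour at (lon, lat, t[days])
  vel_deg <- function(p_lon, p_lat, t) {
    u <- interp_field(vel, "u", p_lon, p_lat, t)
    v <- interp_field(vel, "v", p_lon, p_lat, t)
    list(
      dlon = u * 3.6 / (KM_PER_DEG * cos(deg2rad(p_lat))),
      dlat = v * 3.6 / KM_PER_DEG
    )
  }

  elapsed <- 0
  for (s in seq_len(nstep)) {
    h <- min(step_hours, total_h - elapsed)
    act <- !flagged
    if (!any(act)) break
    x <- lon[act]; y <- lat[act]
    t0 <- t_start + sgn * elapsed / 24
    hd <- sgn * h            # signed step in hours
    k1 <- vel_deg(x, y, t0)
    k2 <- vel_deg(x + hd / 2 * k1$dlon, y + hd / 2 * k1$dlat, t0 + sgn * h / 48)
    k3 <- vel_deg(x + hd / 2 * k2$dlon, y + hd / 2 * k2$dlat, t0 + sgn * h / 48)
    k4 <- vel_deg(x + hd * k3$dlon, y + hd * k3$dlat, t0 + sgn * h / 24)
    nx <- x + hd / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon)
    ny <- y + hd / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat)
    out <- !in_domain(vel, nx, ny)
    # frozen at last in-domain position
    nx[out] <- x[out]; ny[out] <- y[out]
    lon[act] <- nx; lat[act] <- ny
    flagged[act] <- flagged[act] | out
    elapsed <- elapsed + h
  }
  list(lon = lon, lat = lat, flagged = flagged)
}
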