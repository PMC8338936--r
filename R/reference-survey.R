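# The reference synthetic survey: the documented stand-in world on which the
# front-biomass statistics are exercised end to end.

#' Build the reference synthetic survey
#'
#' One self-contained world: an energetic mesoscale eddy field on a Southern
#' Ocean domain (30-54 E, 56-44 S), stirred SST and chlorophyll, backward
#' FSLE (60-day horizon: any value at or above ln(10)/60 ~ 0.038/day — in
#' particular everything near the 0.08/day front threshold — is resolved
#' exactly), and a zig-zag winter ship transect of about 4200 acoustic units
#' whose latent AFC follows the limiting-factor law with front-effect slope 3
#' gated at 0.22 mg/m^3 chlorophyll. Day/night flags are assigned from solar
#' elevation; the front statistics use the night subset (about 2900 units).
#'
#' @param seed integer seed; field and transect draws are derived from it.
#' @param slope front-effect slope (default 3; 0 for a null world).
#' @param baseline_noise baseline multiplier half-width (default 0; use a
#'   positive value, e.g. 0.5, for a non-degenerate null world).
#' @param fields optional precomputed field set (as returned in `$fields`) to
#'   reuse across transect redraws.
#' @return list with `fields` (list: `vel`, `fsle`, `sst_grad`, `chl`),
#'   `transect` (all units, with `afc` from [compute_afc()]), `night` (the
#'   night subset), and `spec` (the transect spec).
#' @export
reference_survey <- function(seed = 1, slope = 3, baseline_noise = 0,
                             fields = NULL) {
  if (is.null(fields)) {
    espec <- eddy_field_spec(seed = seed + 41L)
    vel <- gen_velocity_field(espec)
    fsle <- compute_fsle(vel, params = fsle_params(horizon_days = 60))
    sc <- gen_scalar_fields(vel, espec)
    fields <- list(vel = vel, fsle = fsle,
                   sst_grad = compute_sst_gradient(sc$sst), chl = sc$chl)
  }
  wp <- data.frame(lon = c(31, 36, 41, 46, 53),
                   lat = c(-55, -45, -55, -45, -54))
  spec <- transect_spec(
    wp, start_time = as.POSIXct("2014-06-20 12:00:00", tz = "UTC"),
    slope = slope, chl_gate = 0.22, baseline_noise = baseline_noise,
    seed = seed + 6L
  )
  tr <- gen_transect(spec, fields$fsle, fields$sst_grad, fields$chl)
  tr$afc <- compute_afc(tr)
  list(fields = fields, transect = tr,
       night = tr[tr$daynight == "night", , drop = FALSE], spec = spec)
}

#' Closed-form conditional-quantile slope of the reference survey
#'
#' Under the limiting-factor law with constant baseline `b`, slope `s` and a
#' chlorophyll gate passed by a fraction `pi` of the water (independent of
#' the diagnostic), the conditional tau-quantile of AFC given the diagnostic
#' `d` is exactly `b + s d (tau - 1 + pi) / pi` for `tau > 1 - pi` (and `b`
#' otherwise): the ground truth that raw-scale quantile regression must
#' recover.
#'
#' @param tau quantile level(s).
#' @param slope generative front-effect slope `s`.
#' @param rich_fraction gate pass fraction `pi`.
#' @return generative quantile slope(s).
#' @export
generative_quantile_slope <- function(tau, slope, rich_fraction) {
  ifelse(tau > 1 - rich_fraction,
         slope * (tau - 1 + rich_fraction) / rich_fraction, 0)
}
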