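# Analytic test flows and memoised fixtures shared across test files.

KM <- frontfish:::KM_PER_DEG

# pure strain u = gamma x, v = -gamma y (x, y metres from (0,0)); FSLE of
# this flow is exactly gamma: separations grow as exp(gamma t)
strain_field <- function(gamma_per_day = 0.1, half_deg = 8, spacing = 0.1) {
  g <- gamma_per_day / 86400
  lon <- seq(-half_deg, half_deg, by = spacing)
  lat <- seq(-half_deg, half_deg, by = spacing)
  field_from_function(
    lon, lat, 0,
    u = function(lo, la, t) g * lo * KM * 1000 * cos(la * pi / 180),
    v = function(lo, la, t) -g * la * KM * 1000
  )
}

# solid-body rotation about (0, 0) with period `period_days`
rotation_field <- function(period_days = 10, half_deg = 2, spacing = 0.05) {
  om <- 2 * pi / (period_days * 86400)
  lon <- seq(-half_deg, half_deg, by = spacing)
  lat <- seq(-half_deg, half_deg, by = spacing)
  field_from_function(
    lon, lat, 0,
    u = function(lo, la, t) -om * la * KM * 1000,
    v = function(lo, la, t) om * lo * KM * 1000 * cos(la * pi / 180)
  )
}

# uniform scalar field helper
uniform_field <- function(value, var = "sst", half_deg = 1, spacing = 0.05) {
  lon <- seq(-half_deg, half_deg, by = spacing)
  lat <- seq(-half_deg, half_deg, by = spacing)
  args <- list(lon, lat, 0)
  args[[var]] <- function(lo, la, t) rep(value, length(lo))
  do.call(field_from_function, args)
}

# the reference synthetic survey, computed once per test run
.world_cache <- new.env(parent = emptyenv())
reference_world <- function() {
  if (is.null(.world_cache$w)) .world_cache$w <- reference_survey(seed = 1)
  .world_cache$w
}
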