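# Synthetic generators: velocity fields, stirred scalars, transects.

test_that("zero-amplitude eddy spec gives a zero velocity field", {
  spec <- eddy_field_spec(n_eddies = 5, amplitude_range = c(0, 0), seed = 3)
  vel <- gen_velocity_field(spec)
  expect_equal(max(abs(vel$data$u)), 0)
  expect_equal(max(abs(vel$data$v)), 0)
})

test_that("a single Gaussian eddy peaks at A exp(-1/2) / R on the r = R circle", {
  A <- 15000; R_km <- 50
  spec <- eddy_field_spec(lon_range = c(-3, 3), lat_range = c(-3, 3),
                          spacing = 0.02, n_eddies = 1,
                          amplitude_range = c(A, A),
                          radius_range = c(R_km, R_km), seed = 1)
  vel <- gen_velocity_field(spec)
  speed <- sqrt(vel$data$u^2 + vel$data$v^2)
  expect_equal(max(speed), A * exp(-0.5) / (R_km * 1000), tolerance = 0.01)
  # and the maximum sits at distance ~R from the eddy centre
  grid <- expand.grid(lon = vel$lon, lat = vel$lat)
  i <- which.max(speed)
  ctr <- frontfish:::with_seed(1, {
    runif(1, 0, 2 * pi)   # eddy drift direction, drawn first
    data.frame(lon = runif(1, -3, 3), lat = runif(1, -3, 3))
  })
  r_at_max <- frontfish:::dist_km(grid$lon[i], grid$lat[i], ctr$lon, ctr$lat)
  expect_equal(r_at_max, R_km, tolerance = 0.05)
})

test_that("generated velocity fields are discretely divergence-free", {
  spec <- eddy_field_spec(seed = 11)
  vel <- gen_velocity_field(spec)
  u <- vel$data$u[, , 1]; v <- vel$data$v[, , 1]
  lat0 <- mean(spec$lat_range)
  dx <- spec$spacing * KM * 1000 * cos(lat0 * pi / 180)
  dy <- spec$spacing * KM * 1000
  nx <- nrow(u); ny <- ncol(u)
  div <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * dx) +
    (v[2:(nx - 1), 3:ny] - v[2:(nx - 1), 1:(ny - 2)]) / (2 * dy)
  gradu <- (u[3:nx, 2:(ny - 1)] - u[1:(nx - 2), 2:(ny - 1)]) / (2 * dx)
  expect_lt(max(abs(div)), 1e-6 * max(abs(gradu)))
})

test_that("identical seeds give bit-identical fields; spec validation works", {
  spec <- eddy_field_spec(seed = 5)
  expect_identical(gen_velocity_field(spec), gen_velocity_field(spec))
  expect_error(eddy_field_spec(spacing = 0), "spacing")
  expect_error(eddy_field_spec(lon_range = c(10, 10)), "empty domain")
  expect_error(eddy_field_spec(radius_range = c(0, 10)), "radii")
})

test_that("scalar ramp is unchanged by a zero flow and its gradient is the ramp slope", {
  spec <- eddy_field_spec(lon_range = c(-2, 2), lat_range = c(-2, 2),
                          spacing = 0.1, n_eddies = 0, seed = 1)
  vel <- gen_velocity_field(spec)
  sc <- gen_scalar_fields(vel, spec, advect_days = 10, sst_ramp = 0.009,
                          n_patches = 0)
  gr <- compute_sst_gradient(sc$sst)
  expect_equal(max(abs(gr$data$grad - 0.009)), 0, tolerance = 1e-10)
  expect_error(gen_scalar_fields(vel, spec, advect_days = 0), "advect_days")
})

test_that("strain flow amplifies the SST gradient like exp(gamma t)", {
  # ramp perpendicular to the compressing axis of u = gx, v = -gy
  vel <- strain_field(0.1, half_deg = 6, spacing = 0.1)
  spec <- eddy_field_spec(lon_range = c(-6, 6), lat_range = c(-6, 6),
                          spacing = 0.1, n_eddies = 0, seed = 1)
  base <- 0.002
  for (days in c(5, 10)) {
    sc <- gen_scalar_fields(vel, spec, advect_days = days, sst_ramp = base,
                            n_patches = 0)
    gr <- compute_sst_gradient(sc$sst)
    # centre of the domain: clean exponential amplification
    mid <- round(length(vel$lon) / 2)
    expect_equal(gr$data$grad[mid, mid, 1], base * exp(0.1 * days),
                 tolerance = 0.02)
  }
})

test_that("chlorophyll-rich mask is empty when patches stay under the threshold", {
  spec <- eddy_field_spec(lon_range = c(-2, 2), lat_range = c(-2, 2),
                          spacing = 0.1, n_eddies = 0, seed = 1)
  vel <- gen_velocity_field(spec)
  sc <- gen_scalar_fields(vel, spec, advect_days = 5, chl_background = 0.05,
                          n_patches = 4, patch_amplitude_range = c(0.01, 0.05))
  expect_false(any(sc$chl$data$chl > 0.22))
})

test_that("transect AFC follows the limiting-factor law with exact uniform quantiles", {
  # gate disabled: conditional 90th percentile is baseline + 0.9 slope diag
  lon <- seq(-1, 1, by = 0.05); lat <- seq(-1, 1, by = 0.05)
  diag_fun <- function(lo, la, t) 0.05 + 0.1 * (lo + 1) # 0.05 .. 0.25
  fsle <- field_from_function(lon, lat, 0, fsle = diag_fun)
  chl <- field_from_function(lon, lat, 0, chl = function(lo, la, t) rep(0.5, length(lo)))
  wp <- data.frame(lon = c(-0.9, 0.9), lat = c(0, 0))
  spec <- transect_spec(wp, spacing_km = 0.05, baseline = 1, slope = 3,
                        chl_gate = 0, seed = 2)
  tr <- gen_transect(spec, fsle, NULL, chl)
  tr$afc <- compute_afc(tr)
  expect_equal(tr$afc, tr$true_afc)
  fit <- quantile_regression(tr$fsle, tr$afc, taus = 0.9, scale = "raw",
                             n_boot = 200, seed = 1)
  expect_gt(fit$slope_hi, 0.9 * 3 * 0.93)
  expect_lt(fit$slope_lo, 0.9 * 3 * 1.07)
  # with slope 0 the AFC is independent of the diagnostic
  tr0 <- gen_transect(transect_spec(wp, spacing_km = 0.05, slope = 0,
                                    chl_gate = 0, seed = 2), fsle, NULL, chl)
  expect_equal(stats::var(tr0$true_afc), 0)
})

test_that("transects are deterministic under a seed and reject stray waypoints", {
  lon <- seq(-1, 1, by = 0.1); lat <- seq(-1, 1, by = 0.1)
  fsle <- field_from_function(lon, lat, 0, fsle = function(lo, la, t) abs(lo) / 10)
  chl <- field_from_function(lon, lat, 0, chl = function(lo, la, t) rep(0.3, length(lo)))
  wp <- data.frame(lon = c(-0.5, 0.5), lat = c(-0.5, 0.5))
  spec <- transect_spec(wp, seed = 9)
  expect_identical(gen_transect(spec, fsle, NULL, chl),
                   gen_transect(spec, fsle, NULL, chl))
  wp_bad <- data.frame(lon = c(-0.5, 3), lat = c(-0.5, 0.5))
  expect_error(gen_transect(transect_spec(wp_bad, seed = 9), fsle, NULL, chl),
               "waypoint 2")
})

test_that("field and transect CSV round-trips are lossless", {
  vel <- gen_velocity_field(eddy_field_spec(
    lon_range = c(0, 1), lat_range = c(0, 1), spacing = 0.25, n_eddies = 2,
    seed = 4))
  p <- tempfile(fileext = ".csv")
  write_field_csv(vel, p)
  back <- read_field_csv(p)
  expect_equal(back$data$u, vel$data$u)
  expect_equal(back$lon, vel$lon)

  lon <- seq(-1, 1, by = 0.1)
  fsle <- field_from_function(lon, lon, 0, fsle = function(lo, la, t) abs(lo))
  chl <- field_from_function(lon, lon, 0, chl = function(lo, la, t) rep(0.3, length(lo)))
  tr <- gen_transect(transect_spec(data.frame(lon = c(-0.5, 0.5),
                                              lat = c(0, 0)), seed = 1),
                     fsle, NULL, chl)
  p2 <- tempfile(fileext = ".csv")
  write_transect_csv(tr, p2)
  tr2 <- read_transect_csv(p2)
  expect_equal(tr2$layer_05, tr$layer_05)
  expect_equal(as.numeric(tr2$time), as.numeric(tr$time))
})
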