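# Lagrangian diagnostics: advection, FSLE, SST gradient, colocation.

test_that("advection in a zero flow leaves positions unchanged", {
  vel <- uniform_field(0, "u")
  vel$data$v <- vel$data$u
  res <- advect(vel, c(-0.3, 0.2), c(0.1, -0.4), 0, duration_days = 5)
  expect_equal(res$lon, c(-0.3, 0.2))
  expect_equal(res$lat, c(0.1, -0.4))
  expect_false(any(res$flagged))
})

test_that("a 0.1 m/s zonal flow displaces 8.64 km east per day at the equator", {
  lon <- seq(-1, 1, by = 0.1); lat <- seq(-1, 1, by = 0.1)
  vel <- field_from_function(lon, lat, 0,
                             u = function(lo, la, t) rep(0.1, length(lo)),
                             v = function(lo, la, t) rep(0, length(lo)))
  res <- advect(vel, 0, 0, 0, duration_days = 1)
  km_east <- (res$lon - 0) * KM
  expect_equal(km_east, 8.64, tolerance = 1e-4)
  expect_equal(res$lat, 0)
  # backward in time: same displacement west
  resb <- advect(vel, 0, 0, 0, duration_days = -1)
  expect_equal((resb$lon) * KM, -8.64, tolerance = 1e-4)
})

test_that("a solid-body orbit closes to within 1e-3 of its radius", {
  vel <- rotation_field(period_days = 10)
  r0 <- 0.5
  res <- advect(vel, r0, 0, 0, duration_days = 10, step_hours = 6)
  err <- sqrt((res$lon - r0)^2 + res$lat^2)
  expect_lt(err, 1e-3 * r0)
})

test_that("particles leaving the domain are frozen and flagged, not an error", {
  lon <- seq(-1, 1, by = 0.1); lat <- seq(-1, 1, by = 0.1)
  vel <- field_from_function(lon, lat, 0,
                             u = function(lo, la, t) rep(1, length(lo)),
                             v = function(lo, la, t) rep(0, length(lo)))
  res <- advect(vel, 0.9, 0, 0, duration_days = 10)
  expect_true(res$flagged)
  expect_lte(res$lon, 1)
})

test_that("FSLE of a uniform translation flow is zero", {
  lon <- seq(-2, 2, by = 0.1)
  vel <- field_from_function(lon, lon, 0,
                             u = function(lo, la, t) rep(0.2, length(lo)),
                             v = function(lo, la, t) rep(0.1, length(lo)))
  f <- compute_fsle(vel, lon_out = seq(-0.5, 0.5, by = 0.25),
                    lat_out = seq(-0.5, 0.5, by = 0.25),
                    params = fsle_params(horizon_days = 5))
  expect_equal(max(f$data$fsle), 0)
})

test_that("FSLE of a pure strain flow recovers the strain rate within 5%", {
  vel <- strain_field(0.1)
  f <- compute_fsle(vel, lon_out = seq(-0.5, 0.5, length.out = 12),
                    lat_out = seq(-0.5, 0.5, length.out = 12),
                    params = fsle_params(horizon_days = 60))
  v <- as.vector(f$data$fsle)
  expect_true(all(abs(v - 0.1) / 0.1 < 0.05))
})

test_that("FSLE depends on delta0, deltaf only through their ratio, and on
           direction not at all, for time-independent strain", {
  vel <- strain_field(0.1)
  out <- list(lon = seq(-0.4, 0.4, length.out = 5),
              lat = seq(-0.4, 0.4, length.out = 5))
  f1 <- compute_fsle(vel, out$lon, out$lat,
                     fsle_params(0.04, 0.4, horizon_days = 60))
  f2 <- compute_fsle(vel, out$lon, out$lat,
                     fsle_params(0.08, 0.8, horizon_days = 60))
  expect_equal(f1$data$fsle, f2$data$fsle, tolerance = 0.02)
  ff <- compute_fsle(vel, out$lon, out$lat,
                     fsle_params(horizon_days = 60, direction = "forward"))
  expect_equal(f1$data$fsle, ff$data$fsle, tolerance = 1e-12)
})

test_that("the 0.08/day front threshold is the 28.8-day crossing rate", {
  # a pair reaching 0.4 deg from 0.04 deg in 28.8 days
  expect_equal(log(0.4 / 0.04) / 28.8, 0.08, tolerance = 0.001)
})

test_that("fsle_params validates its invariants", {
  expect_error(fsle_params(delta0 = 0.5, deltaf = 0.4), "delta0")
  expect_error(fsle_params(step_hours = 0), "step")
  lon <- seq(0, 0.3, by = 0.1)
  vel <- field_from_function(lon, lon, 0,
                             u = function(lo, la, t) rep(0, length(lo)),
                             v = function(lo, la, t) rep(0, length(lo)))
  expect_error(compute_fsle(vel, params = fsle_params(deltaf = 0.4)),
               "domain")
})

test_that("SST gradient: uniform field gives zero; meridional ramp gives its slope", {
  uni <- uniform_field(12, "sst")
  g <- compute_sst_gradient(uni)
  expect_equal(max(g$data$grad), 0)

  # SST = 0.009 degC per northward km: the reference thermal front threshold
  lon <- seq(-2, 2, by = 0.05); lat <- seq(-2, 2, by = 0.05)
  ramp <- field_from_function(lon, lat, 0,
    sst = function(lo, la, t) 0.009 * la * KM)
  g2 <- compute_sst_gradient(ramp)
  expect_equal(as.vector(g2$data$grad), rep(0.009, length(g2$data$grad)),
               tolerance = 1e-12)
  expect_error(compute_sst_gradient(gridded_field(c(0, 1), c(0, 1),
    data = list(sst = array(0, c(2, 2, 1))))), "3 cells")
})

test_that("the gradient operator is linear at component level", {
  lon <- seq(-1, 1, by = 0.1)
  f1 <- field_from_function(lon, lon, 0,
                            sst = function(lo, la, t) sin(lo) + la^2)
  f2 <- field_from_function(lon, lon, 0,
                            sst = function(lo, la, t) cos(2 * la) * lo)
  comb <- field_from_function(lon, lon, 0,
    sst = function(lo, la, t) 2 * (sin(lo) + la^2) - 3 * (cos(2 * la) * lo))
  g1 <- compute_sst_gradient(f1); g2 <- compute_sst_gradient(f2)
  gc <- compute_sst_gradient(comb)
  expect_equal(gc$data$gx, 2 * g1$data$gx - 3 * g2$data$gx, tolerance = 1e-12)
  expect_equal(gc$data$gy, 2 * g1$data$gy - 3 * g2$data$gy, tolerance = 1e-12)
})

test_that("colocation averages a disc: uniform field, half-plane, missing value", {
  uni <- uniform_field(3.7, "sst")
  expect_equal(colocate(uni, "sst", 0.1, -0.2), 3.7)
  # half-plane: 0 west of the meridian, 1 east; point on the meridian
  # (cell centres offset half a cell so none sits exactly on the meridian)
  lon <- seq(-0.995, 1.005, by = 0.01); lat <- seq(-1, 1, by = 0.01)
  half <- field_from_function(lon, lat, 0,
                              sst = function(lo, la, t) as.numeric(lo > 0))
  v <- colocate(half, "sst", 0, 0, params = colocation_params(0.2))
  expect_equal(v, 0.5, tolerance = 0.02)
  # no qualifying cell: missing marker, not an error
  expect_true(is.na(colocate(uni, "sst", 5, 5,
                             params = colocation_params(0.2))))
  expect_error(colocation_params(0), "sigma")
})
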