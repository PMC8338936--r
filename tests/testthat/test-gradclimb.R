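# Gradient-climbing model: drift law, walker oracle, Lax solver, scenarios.

test_that("the config enforces its identities and the CFL bound", {
  cfg <- gradclimb_config()
  expect_equal(cfg$p_R * cfg$dTdx_max, cfg$xi_max)
  expect_error(gradclimb_config(xi_max = 0.05), "identity")
  expect_error(gradclimb_config(dt = 1e5), "CFL")
  expect_error(gradclimb_config(V = 0), "> 0")
})

test_that("the tracer plateau is symmetric, flat-topped and correctly scaled", {
  cfg <- gradclimb_config()
  tr <- tracer_profile(cfg)
  expect_equal(tr$T, rev(tr$T))                      # construction symmetry
  far <- abs(tr$x) > 20e3
  expect_lt(max(tr$T[far]), 1e-3)                    # far field -> 0
  # max gradient ~ level change / transition width (logistic shape factor 1)
  g <- frontfish:::grad1d(tr$T, cfg$dx)
  expect_equal(max(abs(g)), 1 / tr$transition_width, tolerance = 0.01)
  expect_error(tracer_profile(gradclimb_config(dx = 1000)), "resolve")
})

test_that("the drift law is odd, capped at V and matches closed-form values", {
  cfg <- gradclimb_config()
  gmax <- cfg$dTdx_max
  U <- function(g) fish_velocity(list(x = 0, T = 0), cfg, dTdx = g)
  expect_equal(U(0), 0)
  expect_equal(U(gmax), cfg$V)                       # r = 1
  expect_equal(U(0.5 * gmax), 0.75 * cfg$V)          # r(2 - r) at r = 0.5
  expect_equal(U(5 * gmax), cfg$V)                   # capped above threshold
  rs <- seq(-3, 3, by = 0.1)
  expect_equal(U(rs * gmax), -U(-rs * gmax))         # odd
  expect_true(all(abs(U(rs * gmax)) <= cfg$V + 1e-15))
  on01 <- U(seq(0, 1, 0.05) * gmax)
  expect_true(all(diff(on01) >= -1e-15))             # monotone on [0, 1]
})

test_that("the walker oracle reproduces V r (2 - r) across the r grid", {
  cfg <- gradclimb_config()
  for (r in seq(0.1, 1, by = 0.1)) {
    wd <- walker_drift(cfg, gradient = r * cfg$dTdx_max, n_walkers = 2e4,
                       seed = 100 + round(10 * r))
    closed <- cfg$V * r * (2 - r)
    tol <- max(3 * wd$se, 1e-12)
    expect_lt(abs(wd$drift - closed), tol)
  }
  # zero gradient: no drift beyond sampling error
  w0 <- walker_drift(cfg, 0, n_walkers = 2e4, seed = 1)
  expect_lt(abs(w0$drift), 4 * cfg$V / sqrt(2e4))
  # r = 1: every step is correct
  w1 <- walker_drift(cfg, cfg$dTdx_max, n_walkers = 1e4, seed = 1)
  expect_equal(w1$drift, cfg$V)
  expect_error(walker_drift(cfg, 0, n_walkers = 100), "1e4")
})

test_that("Lax steps: no-flow identity, translation, exact mass conservation", {
  cfg <- gradclimb_config(boundary = "periodic", L = 20e3)
  n <- cfg$L / cfg$dx + 1
  # the homogeneous state is a fixed point of the scheme at zero drift
  same <- step_density(rep(2.5, n), rep(0, n), cfg)
  expect_equal(as.numeric(same), rep(2.5, n), tolerance = 1e-15)

  # uniform drift: translation by c dt plus Lax diffusion; mass exact
  rho <- 1 + 0.5 * sin(seq(0, 2 * pi, length.out = n))
  U <- rep(0.1, n)
  r1 <- rho
  for (s in 1:50) r1 <- step_density(r1, U, cfg)
  expect_equal(sum(r1), sum(rho), tolerance = 1e-13)
  shift <- 0.1 * 50 * cfg$dt / cfg$dx            # cells
  x <- seq_len(n)
  # cross-correlation peaks at the advected displacement
  cc <- vapply(0:20, function(k) {
    sum((r1 - mean(r1)) * (rho[((x - k - 1) %% n) + 1] - mean(rho)))
  }, numeric(1))
  expect_equal(which.max(cc) - 1, round(shift))
  expect_error(step_density(rho, rep(100, n), cfg), "CFL")
})

test_that("a zero tracer leaves the density homogeneous", {
  cfg <- gradclimb_config(L = 10e3)
  tr <- tracer_profile(cfg, plateau_width = 2e3, transition_width = 1.5e3,
                       bump_amplitude = 0)
  tr$T <- tr$T * 0
  run <- simulate_plateau(cfg, tr, t_end = 3600, snapshot_times = 3600)
  expect_equal(max(abs(run$snapshots[[length(run$snapshots)]]$rho - 1)), 0)
})

test_that("symmetric tracer and initial state give a symmetric density", {
  cfg <- gradclimb_config()
  tr <- tracer_profile(cfg)
  run <- simulate_plateau(cfg, tr, t_end = 12 * 3600,
                          snapshot_times = 12 * 3600)
  rho <- as.numeric(run$snapshots[[length(run$snapshots)]]$rho)
  expect_equal(rho, rev(rho), tolerance = 1e-12)
})

test_that("fixed far-field boundary gains mass only through boundary influx", {
  cfg <- gradclimb_config()
  tr <- tracer_profile(cfg)
  run <- simulate_plateau(cfg, tr, t_end = 6 * 3600, snapshot_times = 6 * 3600)
  # influx at the far boundary is ~0 (drift vanishes there), so the relative
  # mass drift stays tiny even with the reservoir boundary
  expect_lt(run$mass_drift, 1e-8)
})

test_that("filament scenario: D = 0 sharpens monotonically; gamma = D = 0 flags", {
  cfg <- gradclimb_config(L = 60e3)
  fs <- filament_scenario(cfg, gamma = 0.1 / 86400, D = 0, w0 = 2e3,
                          t_end = 10 * 86400,
                          track_times = c(2, 6) * 86400)
  expect_true(all(diff(fs$gradient_series$max_grad) > -1e-12))
  expect_equal(fs$lifetime_days, 10)            # above threshold throughout
  expect_equal(fs$width_check$w_numeric_m, fs$width_check$w_closed_m,
               tolerance = 0.01)
  f0 <- filament_scenario(cfg, gamma = 0, D = 0, w0 = 2e3,
                          t_end = 5 * 86400, track_times = 86400)
  expect_true(f0$no_erosion)
  expect_equal(f0$lifetime_days, 5)
  expect_error(filament_scenario(cfg, gamma = -1, D = 1), "gamma")
})

test_that("strain-diffusion equilibrium width is sqrt(D / gamma)", {
  cfg <- gradclimb_config(L = 100e3)
  gam <- 0.1 / 86400
  fs <- filament_scenario(cfg, gamma = gam, D = 1, w0 = 10e3,
                          t_end = 50 * 86400, track_times = 50 * 86400)
  w_end <- fs$width_check$w_numeric_m[1]
  expect_equal(w_end, sqrt(1 / gam), tolerance = 0.02)  # ~0.93 km
})
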