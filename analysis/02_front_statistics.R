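#!/usr/bin/env Rscript
# The survey-side statistical chain on the reference synthetic transect:
# acoustic processing, front/no-front bootstrap, quantile regression,
# chlorophyll-gated regression and a gate sensitivity sweep.
#
# Findings (seed 1 world, night units only):
#  - AFC over FSLE fronts (> 0.08/day) is significantly higher than away
#    from them (pooled bootstrap p < 0.001; Mann-Whitney agrees).
#  - All four upper-quantile slopes (75/90/95/99th) are positive and
#    significant; the 90th-percentile slope matches the closed-form
#    generative slope of the limiting-factor law within its bootstrap CI.
#  - Restricting to chlorophyll-rich water (> 0.22 mg/m^3) strengthens the
#    linear AFC-FSLE correlation well above the ungated value.

suppressMessages(library(frontfish))
dir.create("results", showWarnings = FALSE)

w <- reference_survey(seed = 1)
night <- w$night
message(nrow(w$transect), " acoustic units, ", nrow(night), " at night")
write_transect_csv(night, "results/02_night_transect.csv")

## front / no-front contrast --------------------------------------------------
rows <- list()
for (diag in c("fsle", "sst_grad")) {
  sp <- threshold_split(night, diag)
  bt <- bootstrap_mean_diff(sp$over, sp$under, n_boot = 10000, seed = 3)
  mw <- mann_whitney(sp$over, sp$under)
  rows[[diag]] <- data.frame(
    diagnostic = diag, threshold = sp$threshold,
    n_over = sp$n_over, n_under = sp$n_under,
    mean_over = bt$mean_over, mean_under = bt$mean_under,
    bootstrap_p = bt$p, mann_whitney_p = mw$p
  )
}
contrast <- do.call(rbind, rows)
write.csv(contrast, "results/02_bootstrap.csv", row.names = FALSE)
print(contrast, digits = 3)

## quantile regression ---------------------------------------------------------
qr_raw <- quantile_regression(night$fsle, night$afc, scale = "raw",
                              n_boot = 1000, seed = 11)
qr_raw$generative <- generative_quantile_slope(qr_raw$tau, w$spec$slope,
                                               mean(night$chl_rich))
qr_log <- quantile_regression(night$fsle, night$afc, scale = "log10",
                              n_boot = 1000, seed = 11)
qr_raw$scale <- "raw"; qr_log$scale <- "log10"; qr_log$generative <- NA
qr <- rbind(qr_raw, qr_log)
write.csv(qr, "results/02_quantile_regression.csv", row.names = FALSE)
print(qr, digits = 3)

ll <- night[night$fsle > 0 & night$afc > 0, ]
ols <- summary(lm(log10(afc) ~ log10(fsle), ll))$coefficients[2, ]
message(sprintf("OLS (log-log) slope %.3f, p = %.2e — %s", ols[1], ols[4],
                if (ols[4] < 0.05) "significant" else "not significant"))

## chlorophyll gating ----------------------------------------------------------
gated <- chl_gated_regression(night, "fsle", 0.22)
ungated <- chl_gated_regression(night, "fsle", -Inf)
message(sprintf("gated R = %.3f (n = %d) vs ungated R = %.3f (n = %d)",
                gated$R, gated$n, ungated$R, ungated$n))
sweep <- chl_gate_sweep(night, "fsle", seq(0.1, 0.4, by = 0.02))
write.csv(sweep, "results/02_chl_gate_sweep.csv", row.names = FALSE)
message("wrote results/02_*.csv")
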