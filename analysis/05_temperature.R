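#!/usr/bin/env Rscript
# Temperature layer: generate monitoring sites, screen them to reference
# (least-disturbed) condition, predict mean July-August temperature for all
# reaches with a random forest (qwsa excluded by design), scan Jenks
# partitions for a parsimonious class count, and bin reaches with the
# packaged temperature thresholds.

library(streamclass)

SEED <- 2026
net <- read_network("results/network/reaches.csv", "results/network/fromto.csv")

sites <- generate_temperature_sites(net, n_sites = 2000, noise_sd = 1,
                                    seed = SEED + 2000)
ref <- screen_reference_sites(sites)
log <- attr(ref, "screen_log")
cat("sites:", nrow(sites$sites), "| reference after screening:",
    nrow(ref$sites), "\n")
cat("rejection reasons:\n")
print(table(log$reason))

mod <- fit_temperature_regressor(ref, seed = SEED + 2001)
cat(sprintf("\nOOB variance explained: %.1f%%  OOB MSE: %.2f\n",
            100 * mod$oob_r2, mod$oob_mse))

pred <- predict_temperature(mod, net)
cat(sprintf("predicted July-August temperature: mean %.1f C, range %.1f-%.1f C\n",
            mean(pred), min(pred), max(pred)))

k <- select_parsimonious_k(unname(pred), 2:12)
diag <- attr(k, "diagnostics")
cat("parsimonious Jenks class count:", as.integer(k), "\n")

def <- default_thresholds()$temperature
tab <- data.frame(COMID = net$reaches$comid,
                  predicted_ja_temp = unname(pred),
                  temp_class = assign_interval_classes(pred, def$breaks,
                                                       def$labels))
cat("\ntemperature classes (packaged thresholds):\n")
print(table(tab$temp_class))

write.csv(tab, "results/temperature.csv", row.names = FALSE)
write.csv(diag, "results/temperature_jenks_diagnostics.csv", row.names = FALSE)
cat("wrote results/temperature.csv and results/temperature_jenks_diagnostics.csv\n")
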