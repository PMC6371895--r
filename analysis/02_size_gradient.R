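#!/usr/bin/env Rscript
# Size and gradient layer: derive discharge thresholds from the network's
# own order medians (mid-points between consecutive medians), compare with
# the packaged national defaults, and bin every reach.

library(streamclass)

net <- read_network("results/network/reaches.csv", "results/network/fromto.csv")

th <- derive_size_thresholds(net)
print(th)
cat("packaged default breaks (m^3/s):",
    paste(default_thresholds()$size$breaks, collapse = ", "), "\n")

tab_local <- size_gradient_table(net, thresholds = th)
tab_national <- size_gradient_table(net)   # Table-style defaults

cat("\nsize classes, locally derived thresholds:\n")
print(table(tab_local$size_class))
cat("\nsize classes, national default thresholds:\n")
print(table(tab_national$size_class))
cat("\ngradient classes:\n")
print(table(tab_national$gradient_class))

write.csv(tab_national, "results/size_gradient.csv", row.names = FALSE)
cat("wrote results/size_gradient.csv\n")
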