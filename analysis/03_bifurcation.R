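#!/usr/bin/env Rscript
# Network bifurcation layer: junction coding from the from-to topology,
# divergence classes (D1/D2/DU and the generic D for junctions the
# hydrography left undesignated), and split-reach correction via ecological
# units.

library(streamclass)

net <- read_network("results/network/reaches.csv", "results/network/fromto.csv")

tab <- assign_bifurcation_classes(net)
tab <- correct_split_reaches(net, tab)

cat("distinct bifurcation classes:", length(unique(tab$bif_class)), "\n")
cat("most frequent classes:\n")
print(head(sort(table(tab$bif_class), decreasing = TRUE), 10))
cat("\ndivergence classes:\n")
print(table(tab$div_class))
cat("\nreaches flagged as non-sensical junctions:", sum(tab$flagged), "\n")
cat("reaches corrected via ecological units:",
    sum(!is.na(tab$eco_unit_id)), "\n")

write.csv(tab, "results/bifurcation.csv", row.names = FALSE)
cat("wrote results/bifurcation.csv\n")
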