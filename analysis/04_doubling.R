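#!/usr/bin/env Rscript
# CO2 fertilization effect for a doubling of atmospheric CO2 (300 -> 600
# ppm) at constant recycled climate on the default toy globe, with and
# without coordination of photosynthesis. Writes results/doubling.csv.
#
# Run from the repository root: Rscript analysis/04_doubling.R
# (about seven minutes for the two 100-year runs on one CPU)

library(coordphoto)

dir.create("results", showWarnings = FALSE)

message("coordinated run ...")
coord <- run_doubling_experiment(seed = 1, coordination = TRUE)
message("coordination-disabled run ...")
excl <- run_doubling_experiment(seed = 1, coordination = FALSE)

tab <- data.frame(configuration = c("coordinated", "excl_coordination"),
                  gpp_increase_pct = c(coord$percent, excl$percent))
write.csv(tab, "results/doubling.csv", row.names = FALSE)
print(tab, row.names = FALSE)

cat(sprintf("\nCoordination raises the doubling response by %.0f percentage points\n",
            coord$percent - excl$percent))
cat("(the coordination-disabled biosphere, with assimilation pinned to the\n",
    "electron-transport-limited rate, is markedly less CO2-sensitive).\n")
g <- coord$output$aggregate
write.csv(data.frame(year = g$year, ca = coord$output$ca, gpp = g$gpp,
                     leaf_component = g$leaf, lai = g$lai),
          "results/doubling_series.csv", row.names = FALSE)
cat("wrote results/doubling.csv, results/doubling_series.csv\n")
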