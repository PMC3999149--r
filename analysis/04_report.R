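#!/usr/bin/env Rscript

# Summarize the tables written by 02_thresholds.R (and, if present,
# 03_power.R) into the grouped threshold/power report and a bar chart.

library(mvqtlsim)

rep <- report("results")
print(rep)

png("results/power_by_scenario.png", width = 900, height = 520)
plot_power(rep)
dev.off()
message("wrote results/power_by_scenario.png")
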