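#!/usr/bin/env Rscript
# Dosing nomogram: regimens achieving PTA >= 90% per (CRRT stratum, MIC,
# target) cell, ordered by daily dose and infusion burden, with the
# standard-of-care intermittent regimens flagged. Reads the grid written
# by 01_pta_grid.R and writes results/nomogram.csv.

suppressPackageStartupMessages(library(meropk))

grid <- read.csv("results/pta_grid.csv")
nom <- recommend_regimens(grid, threshold = 90)
write.csv(nom, "results/nomogram.csv", row.names = FALSE)

for (crrt in 0:1) {
  for (tg in c(40, 100)) {
    for (mic in c(2, 8)) {
      cell <- nom[nom$crrt == crrt & nom$target == tg & nom$mic == mic, ]
      std <- cell$regimen[cell$standard]
      message(sprintf("CRRT=%d, %3g%% target, MIC %g: %2d regimens pass%s",
                      crrt, tg, mic, nrow(cell),
                      if (length(std)) paste0(" (standard: ",
                                              paste(std, collapse = ", "), ")")
                      else " (no standard regimen passes)"))
    }
  }
}
message("wrote results/nomogram.csv")
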