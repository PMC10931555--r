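#!/usr/bin/env Rscript
# Step 6: composition arithmetic -- weight percent of drug to drug:lipid
# mole ratio (M_drug = 430.53 g/mol, effective surfactant M = 762 g/mol),
# including both readings of the low-dose figure: 0.5 wt% gives ~1:113
# (consistent with the quoted ~1:100), while 0.05 wt% gives ~1:1130.

library(surfbiophys)
source("analysis/00_samples.R")

wt <- c(0.05, 0.5, 2, 4, 8, 10)
tab <- data.frame(
  wt_pct = wt,
  lipid_per_drug = vapply(wt, molar_ratio, numeric(1))
)
tab$ratio_label <- vapply(tab$lipid_per_drug, format_molar_ratio,
                          character(1))
write.csv(tab, "results/composition.csv", row.names = FALSE)

cat("drug:lipid mole ratios:\n")
print(tab, row.names = FALSE, digits = 4)
cat("4 wt% ->", format_molar_ratio(molar_ratio(4)),
    "and 8 wt% ->", format_molar_ratio(molar_ratio(8)),
    "(the quoted breakpoint and saturation compositions);\n")
cat("the ~1:100 low-dose figure matches 0.5 wt% (1:113), not 0.05 wt%",
    "(1:1130) -- both are tabulated rather than guessing intent\n")
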