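#!/usr/bin/env Rscript
# Step 4: gel-to-fluid transition parameters from the duplicate DSC heating
# scans: linear baseline through the 2-8 and 36-40 degC windows, Tm from
# the smoothed peak maximum (~2 degC smoothing for this broad transition),
# dH by trapezoidal integration, FWHM at half height; scans 1 and 3
# averaged per sample.

library(surfbiophys)
source("analysis/00_samples.R")

rows <- lapply(seq_len(nrow(samples)), function(i) {
  s <- samples[i, ]
  fits <- lapply(c(1L, 3L), function(scan) {
    tg <- read_thermogram_csv(
      file.path(sim_dir, sprintf("%s_dsc_scan%d.csv", s$label, scan)),
      scan_id = scan)
    transition_params(baseline_correct(tg, c(2, 8), c(36, 40)),
                      smooth_n = 41L)
  })
  avg <- average_scans(fits)
  data.frame(sample = s$label, wt_pct = s$wt_pct,
             Tm_true = s$Tm, Tm = avg$Tm, Tm_sd = avg$Tm_sd,
             dH_true = s$dH, dH = avg$dH, dH_sd = avg$dH_sd,
             fwhm_true = s$fwhm, fwhm = avg$fwhm, fwhm_sd = avg$fwhm_sd)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/dsc_transition.csv", row.names = FALSE)

cat("transition parameters (mean of scans 1 and 3):\n")
print(tab[, c("sample", "wt_pct", "Tm_true", "Tm", "dH_true", "dH",
              "fwhm")],
      row.names = FALSE, digits = 4)
cat(sprintf("BUD lowers Tm by %.2f degC at 8 wt%% and the enthalpy by %.0f%%
before both recover at 10 wt%% (undissolved crystalline drug)\n",
            tab$Tm[tab$sample == "surf"] - tab$Tm[tab$sample == "bud8"],
            100 * (1 - tab$dH[tab$sample == "bud8"] /
                     tab$dH[tab$sample == "surf"])))
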