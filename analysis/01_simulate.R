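#!/usr/bin/env Rscript
# Step 1: generate the synthetic measurement set for the BUD/surfactant
# dose series -- SANS curves, SAXS/WAXS patterns, duplicate DSC heating
# scans, and pyrene fluorescence spectra/traces -- with known ground truth
# written alongside each raw file.

library(surfbiophys)
source("analysis/00_samples.R")

dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

for (i in seq_len(nrow(samples))) {
  s <- samples[i, ]
  seed <- master_seed + 100L * i
  base <- file.path(sim_dir, s$label)

  p <- sans_model_params(thickness_true = s$d_g, background_B = 0.05,
                         wavelength_spread = 0.10, noise_level = noise,
                         seed = seed + 1L)
  write_dat(gen_sans_curve(p), paste0(base, "_sans.dat"))
  write_ground_truth(p, paste0(base, "_sans_truth.json"))

  cryst <- if (s$crystalline) {
    list(c(13.1, 0.03, 3), c(14.8, 0.03, 2.5), c(14.9, 0.03, 2.2),
         c(16.2, 0.03, 2))
  } else list()
  p <- lamellar_model_params(d_true = s$d, crystalline_peaks = cryst,
                             noise_level = noise, seed = seed + 2L)
  write_dat(gen_saxs_waxs_pattern(p), paste0(base, "_saxs_waxs.dat"))
  write_ground_truth(p, paste0(base, "_saxs_waxs_truth.json"))

  # first and third scans of the heating-cooling-heating regimen
  for (scan in c(1L, 3L)) {
    p <- endotherm_params(Tm_true = s$Tm, dH_true = s$dH,
                          fwhm_true = s$fwhm, baseline_intercept = 0.05,
                          baseline_slope = 0.002, noise_level = 0.002,
                          seed = seed + 10L + scan)
    write_thermogram_csv(gen_thermogram(p),
                         sprintf("%s_dsc_scan%d.csv", base, scan))
    write_ground_truth(p, sprintf("%s_dsc_scan%d_truth.json", base, scan))
  }

  for (probe in c("Pyr4PC", "Pyr10PC")) {
    eta <- if (probe == "Pyr4PC") s$eta4 else s$eta10
    p <- fluorescence_params(eta_true = eta, noise_level = noise,
                             seed = seed + 20L + (probe == "Pyr10PC"))
    fl <- gen_fluorescence(p)
    write_trace_csv(fl$monomer, sprintf("%s_%s_monomer.csv", base, probe))
    write_trace_csv(fl$excimer, sprintf("%s_%s_excimer.csv", base, probe))
    write_trace_csv(fl$spectrum, sprintf("%s_%s_spectrum.csv", base, probe))
    write_ground_truth(p, sprintf("%s_%s_truth.json", base, probe))
  }
}

cat(sprintf("simulated %d samples x 4 modalities into %s (%d files)\n",
            nrow(samples), sim_dir, length(list.files(sim_dir))))
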