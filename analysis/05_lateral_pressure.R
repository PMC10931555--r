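#!/usr/bin/env Rscript
# Step 5: lateral-pressure parameter eta = <I_480> / <I_376> for the two
# bis-pyrenyl probes (Pyr4PC: near-interface, Pyr10PC: near-core) from the
# 120 s time traces, plus band-I-normalised emission spectra.

library(surfbiophys)
source("analysis/00_samples.R")

rows <- list()
for (i in seq_len(nrow(samples))) {
  s <- samples[i, ]
  for (probe in c("Pyr4PC", "Pyr10PC")) {
    mono <- read_trace_csv(
      file.path(sim_dir, sprintf("%s_%s_monomer.csv", s$label, probe)),
      wavelength = 376)
    exci <- read_trace_csv(
      file.path(sim_dir, sprintf("%s_%s_excimer.csv", s$label, probe)),
      wavelength = 480)
    res <- lateral_pressure(exci, mono, probe_label = probe)
    truth <- if (probe == "Pyr4PC") s$eta4 else s$eta10
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s$label, wt_pct = s$wt_pct, probe = probe,
      eta_true = truth, eta = res$eta, eta_sd = res$eta_sd)
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/lateral_pressure.csv", row.names = FALSE)

# normalised emission spectrum of the reference sample, Pyr10PC
sp <- read_spectrum_csv(file.path(sim_dir, "surf_Pyr10PC_spectrum.csv"))
nsp <- normalize_spectrum(sp)
write.csv(data.frame(wavelength_nm = nsp$wavelength, I_norm = nsp$I),
          "results/spectrum_surf_Pyr10PC_normalised.csv", row.names = FALSE)

cat("lateral pressure eta per probe and BUD content:\n")
print(tab, row.names = FALSE, digits = 4)
p4 <- tab[tab$probe == "Pyr4PC", ]
cat(sprintf("Pyr4PC peaks at %g wt%% (breakpoint) and falls beyond it;
Pyr10PC rises to a plateau above ~8 wt%% -- the drug moves deeper into the
hydrophobic core as its content grows\n",
            p4$wt_pct[which.max(p4$eta)]))
cat(sprintf("normalised excimer maximum (Pyr10PC, 0 wt%%): %.1f
(band I = 100)\n", max(nsp$I[nsp$wavelength > 440])))
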