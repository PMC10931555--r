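#!/usr/bin/env Rscript
# Step 2: bilayer thickness from the simulated SANS curves. Incoherent
# background from the 4-5 nm^-1 tail, Kratky-Porod regression over
# 0.31-1.14 nm^-1, d_g = sqrt(12) Rg with slope-propagated uncertainty.

library(surfbiophys)
source("analysis/00_samples.R")

rows <- lapply(seq_len(nrow(samples)), function(i) {
  s <- samples[i, ]
  crv <- read_dat(file.path(sim_dir, paste0(s$label, "_sans.dat")),
                  modality = "SANS")
  sub <- subtract_incoherent_background(crv, tail_window = c(4, 5))
  fit <- kratky_porod_fit(sub, q_window = c(0.31, 1.14))
  v <- guinier_validity(fit)
  data.frame(sample = s$label, wt_pct = s$wt_pct, d_g_true = s$d_g,
             d_g = fit$d_g, d_g_sd = fit$d_g_sd, Rg = fit$Rg, r2 = fit$r2,
             conforming = fit$conforming, qRg_max = v$qRg_max,
             guinier_flag = v$flag,
             background = sub$meta$background_subtracted)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/sans_thickness.csv", row.names = FALSE)

# Kratky-Porod plot table for the reference sample (q^2, ln(I q^2), fit)
crv <- read_dat(file.path(sim_dir, "surf_sans.dat"), modality = "SANS")
sub <- subtract_incoherent_background(crv, c(4, 5))
fit <- kratky_porod_fit(sub)
write.csv(kratky_porod_table(sub, fit), "results/kratky_porod_surf.csv",
          row.names = FALSE)

cat("Kratky-Porod bilayer thickness (all r^2 >= 0.993:",
    all(tab$conforming), ")\n")
print(tab[, c("sample", "wt_pct", "d_g_true", "d_g", "d_g_sd", "r2")],
      row.names = FALSE, digits = 4)
cat(sprintf("max |d_g - truth| = %.4f nm; q.Rg exceeds 1 in every fit (%s),
as expected for ~4 nm bilayers over this window\n",
            max(abs(tab$d_g - tab$d_g_true)), all(tab$guinier_flag)))
cat(sprintf("thickening at 0.5 wt%% BUD: %+.3f nm\n",
            tab$d_g[tab$sample == "bud0.5"] - tab$d_g[tab$sample == "surf"]))
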