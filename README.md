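# surfbiophys

Structural and thermodynamic characterisation of lipid bilayers in an
exogenous pulmonary surfactant (a clinical porcine lung-surfactant extract)
carrying a hydrophobic corticosteroid (budesonide). The package is written
for membrane biophysicists who combine small-angle scattering, calorimetry
and fluorescence on the same vesicle preparations, and who want each
analysis stage to be verifiable by round-trip parameter recovery on
synthetic data with known ground truth.

Four measurement modalities are covered, each with a seeded generator and
an analysis stage:

| modality | quantity | model |
|---|---|---|
| SANS (unilamellar vesicles) | bilayer thickness *d_g* | Kratky–Porod: ln(*I q²*) vs *q²* is linear in the thin-sheet Guinier regime, slope −*R_g*², *d_g* = √12 *R_g* |
| SAXS (multilamellar vesicles) | lamellar repeat distance *d* | Lorentzian diffraction orders on a linear background, *d* = 2π/*q₁*; *d* = *d_L* + *d_W* splits bilayer and water layer |
| WAXS | chain packing / crystalline drug | broad liquid-chain band ~14 nm⁻¹ + sharp residual-run detection |
| DSC | *T_m*, Δ*H*, FWHM of the gel→fluid transition | two-window linear baseline, smoothed peak maximum, trapezoidal area |
| fluorescence | lateral-pressure parameter *η* | pyrene excimer/monomer intensity ratio *η* = ⟨*I*₄₈₀⟩/⟨*I*₃₇₆⟩ with delta-method uncertainty |

Composition arithmetic converts the drug loading in weight percent to a
drug:lipid mole ratio (r = (100/762)/(wt%/430.53) moles of lipid per mole
of drug).

## Worked example

Generate a noise-free SANS curve of a 3.88 nm bilayer, subtract the
incoherent background measured over the 4–5 nm⁻¹ tail, and run the
Kratky–Porod regression over the standard 0.31–1.14 nm⁻¹ window:

```r
library(surfbiophys)
crv <- gen_sans_curve(sans_model_params(thickness_true = 3.88))
fit <- kratky_porod_fit(subtract_incoherent_background(crv))
fit
#> <kratky_porod_result>
#>   Rg  = 1.1201 +/- 0.0000 nm
#>   d_g = 3.8800 +/- 0.0000 nm (d_g = sqrt(12) Rg)
#>   r^2 = 1.00000 (meets threshold 0.993), 112 points, q = 0.31-1.14
#>   warning: max(q) Rg = 1.264 exceeds 1
```

The recovered thickness equals the generating 3.88 nm; the diagnostic warns
that the fit window extends past the nominal Guinier validity *q R_g* < 1,
which is a property of the standard window for ~4 nm bilayers (the slab
oracle in the test suite quantifies the resulting bias). The same pattern —
generate with a known value, analyse, compare — applies to the other
modalities:

```r
fit_lamellar_peaks(gen_saxs_waxs_pattern(lamellar_model_params(d_true = 7.8)), 2)$d
#> [1] 7.800065
water_layer(7.8, 3.9)
#> [1] 3.9
format_molar_ratio(molar_ratio(4))
#> [1] "1:14"
```

## The analysis workflow

`analysis/01_simulate.R` … `07_summary.R` reproduce the full study on a
simulated budesonide dose series (0–10 wt%): simulation, bilayer thickness,
lamellar spacing and crystalline-drug detection, transition parameters with
scan averaging, lateral pressure for both probe depths, composition
arithmetic, and a combined summary. Run them in order from the repository
root; tables land under `results/`.

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

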