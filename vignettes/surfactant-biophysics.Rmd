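---
title: "Models and methods: scattering, calorimetry and excimer fluorescence of surfactant bilayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: scattering, calorimetry and excimer fluorescence of surfactant bilayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfbiophys)
```

This vignette is the package's account of the science it implements: the
models behind each analysis stage, the parameters that matter and their
defaults, what the synthetic-data generators emulate (and what they do
not), and the numerical choices made where the design was genuinely open.

## The system

Exogenous pulmonary surfactant is a clinically administered lipid–protein
extract (here the porcine preparation: ~99 wt% phospholipids, 1–2 wt%
hydrophobic proteins, no cholesterol) that restores the air/liquid
interface of alveoli. Loaded with a water-insoluble corticosteroid
(budesonide, M = 430.53 g/mol), the drug partitions entirely into the lipid
bilayer, and four questions follow: does the bilayer thicken (SANS), does
the lamellar stacking period change (SAXS), does the gel→fluid transition
shift (DSC), and where in the bilayer does the drug sit (pyrene excimer
fluorescence at two probe depths)? Drug loadings are expressed in weight
percent of surfactant mass; `molar_ratio()` converts to a drug:lipid mole
ratio using the conventional effective molar mass of 762 g/mol for the
surfactant (4 wt% ≈ 1:14, 8 wt% ≈ 1:7).

## SANS: bilayer thickness by Kratky–Porod regression

For dilute unilamellar vesicles the interparticle structure factor is ~1
and, for vesicle radii large against 1/q, the bilayer scatters as a thin
sheet. In the Guinier regime (q·R~g~ < 1),

$$ I(q) = C \exp(-q^2 R_g^2)\, q^{-2} + B, $$

with R~g~ the one-dimensional radius of gyration of the thickness profile
and B the flat incoherent background. `kratky_porod_fit()` regresses
ln(I·q²) on q²; the slope is −R~g~², and the sheet thickness is
d~g~ = √12·R~g~ (exact for a uniform slab: R~g~² = L²/12). Defaults follow
the standard protocol for extruded ~80 nm vesicles: background estimated as
the mean intensity over a 4–5 nm⁻¹ tail, fit window 0.31–1.14 nm⁻¹,
conformity flag at r² ≥ 0.993.

Numerical and statistical choices:

* **Weighting.** The default is unweighted ordinary least squares on the
  log scale, matching common practice; `weighted = TRUE` uses weights
  (I/σ)² — the delta-method variance of ln I — and is the estimator whose
  standard errors are interpretable when counting noise is present (the
  test suite's coverage checks use it; unweighted OLS under-covers because
  the log-scale noise grows steeply across the window).
* **Error propagation.** Only the slope standard error is propagated:
  R~g,sd~ = slope~sd~/(2R~g~), d~g,sd~ = √12·R~g,sd~. The
  background-subtraction uncertainty is deliberately not propagated,
  matching how such fits are usually reported.
* **Non-positive intensities** inside the window (over-subtraction) abort
  the fit rather than being dropped: silently dropping the deepest points
  would bias the slope.
* **Guinier validity.** For a ~3.9 nm bilayer the standard window reaches
  q·R~g~ ≈ 1.26–1.28, beyond the nominal validity of the approximation.
  `guinier_validity()` reports the diagnostic and flags it; the package
  does not resolve this tension, it quantifies it — the slab-oracle test
  shows the resulting thickness bias is ~12% for a uniform slab fitted over
  the full window, and that restricting to q·R~g~ ≤ 0.5 recovers L/√12
  within 2%. (For the Guinier-form generator the round trip is exact by
  construction: that test isolates the fitting machinery, not the model
  error.)

The generator (`gen_sans_curve()`) offers three form factors — the Guinier
sheet itself, a uniform slab (squared sinc), and a core–shell hollow sphere
with shell thickness d~g~ and radius 39.5 nm (half the measured 79 nm
hydrodynamic diameter) — plus Gaussian wavelength-spread smearing with
σ~q~ = q·(Δλ/λ)/2.355, treating the stated Δλ/λ = 10% as a FWHM-like spread
(the usual Gaussian surrogate for a velocity-selector triangular
distribution), and counting noise of standard deviation `noise_level`·√I.
Polydispersity is not modelled: thin-sheet analysis is radius-insensitive
over the fitted window.

## SAXS/WAXS: lamellar period and crystalline drug

Multilamellar vesicles produce diffraction orders at q~n~ = 2πn/d.
`fit_lamellar_peaks()` fits each order with a Lorentzian on a linear local
background — the natural lineshape for fluctuation-broadened fluid-lamellar
reflections — in its own window of ±5 half-width guesses around the
detected (or `init_d`-derived) centre; local windows are robust to the
diffuse scattering between orders, which a global fit would have to model.
The repeat distance is d = 2π/q₁ with d~sd~ = 2π·q₁,~sd~/q₁²; the order
ratio q₂/q₁ should be 2.000 for an ideal stack and is reported as a
lamellarity check. `water_layer()` performs the decomposition
d = d~L~ + d~W~ with d~L~ ≅ d~g~ from SANS.

The wide-angle region carries a broad band at ~14 nm⁻¹ from liquid-like
acyl-chain packing. `analyze_waxs()` fits it with a Gaussian on a linear
background, robustly (points beyond 3 residual SD are masked and the fit
repeated, so sharp reflections cannot drag the broad band), then detects
crystalline drug reflections as contiguous runs of positive residual with
z > 4, using the per-point σ where available because counting noise varies
several-fold across the band. Sharp peaks must be narrower than 0.2× the
band width and taller than 2% of the band amplitude (sub-percent residual
structure is the broad-band model's own misfit, not a reflection).
Near-coincident reflections (e.g. 14.8/14.9 nm⁻¹) merge when their widths
overlap; a single-maximum run much wider than its fellows is flagged
`merged` rather than silently reported as one line.

## DSC: transition parameters of a broad endotherm

The gel→fluid transition of a multicomponent surfactant is broad
(FWHM ~12.5 °C), asymmetric and of low cooperativity: overlapping domain
transitions produce an envelope rising gradually from low temperature and
returning to baseline a few degrees above the maximum, well inside the
2–40 °C scan. The generator models this as a split exponential-power peak,

$$ c_p(T) = h\, \exp\!\left(-\ln 2\, \left|\frac{T - T_m}{h_{L,R}}\right|^{\beta}\right), $$

with independent left/right half-widths at half maximum (their log ratio is
the `asymmetry`, default −1), flank exponent β (default 3) and h solved in
closed form so the area equals ΔH exactly. The mode is exactly T~m~ and the
FWHM exactly h~L~ + h~R~, so every recovery test has sharp ground truth;
`asymmetry = 0` with `flank_exponent = 2` is an exact Gaussian
(σ = FWHM/2.3548, height ΔH/(σ√2π)). A skew-normal was considered and
rejected: at this width its Gaussian tails (scale ≈ 10 °C) cannot return to
baseline inside the published scan range, putting several percent of the
peak under the baseline windows and biasing ΔH by ~5% — a shape
contradiction with the measured thermogram, not a tolerance issue. The
generator rejects temperature grids on which the noise-free area misses ΔH
by more than 0.5% (a grid that truncates the peak biases every enthalpy
downstream, regardless of the analysis).

The analysis stage follows the standard integration procedure:
`baseline_correct()` subtracts the line through the mean points of two
flanking windows (defaults 2–8 and 36–40 °C). Because that construction
forces the mean corrected signal in each window to zero, window/peak
overlap is detected from within-window structure instead: a corrected
signal spanning more than 10% of the peak amplitude inside a window raises
an error. `transition_params()` takes T~m~ from the maximum of a
Savitzky–Golay-smoothed curve (quadratic; default 11 points, and ~2 °C —
41 points at the default grid — is the appropriate scale for this broad
transition and is what the workflow and the noisy Monte-Carlo tests use),
refined by a parabola through the three points around the maximum; ΔH by
trapezoidal integration over the full range; FWHM at half the smoothed peak
height by linear interpolation, first crossing on each side of the maximum.
Heating-scan replicates are averaged by `average_scans()` (mean ± SD, the
first/third-scan convention); cooling scans are rejected rather than
silently sign-flipped.

## Fluorescence: lateral pressure from the excimer/monomer ratio

Bis-pyrenyl phosphatidylcholine probes report lateral packing pressure at
the depth of their pyrene moieties (4th vs 10th acyl carbon) through the
relative quantum efficiency of intramolecular excimer formation:
η = ⟨I~excimer~⟩/⟨I~monomer~⟩, the ratio of mean intensities of 120 s time
traces at 480 and 376 nm. η is computed as a ratio of means — not a mean of
per-sample ratios — matching how time-based measurements are averaged, and
its uncertainty is propagated to first order from the two standard errors
of the mean: η~sd~ = η·√((SEM~e~/μ~e~)² + (SEM~m~/μ~m~)²). Whether reported
error bars on such measurements are SDs or SEMs is often ambiguous; the
result records `error_type = "SEM-propagated"` so the choice is explicit.
`normalize_spectrum()` rescales an emission spectrum so the monomer band-I
maximum (located within ±3 nm of 376 nm, tolerating calibration offsets)
equals 100.

The generator builds the spectrum from five narrow Gaussian vibronic bands
(band I at 376 nm) plus one broad excimer band at 480 nm, with the two
scales solved exactly so that I(480)/I(376) = η; the band positions and
relative amplitudes beyond band I are illustrative, as only the 376/480 nm
intensities carry quantitative meaning. Traces are white-noise series —
no photobleaching, drift or lamp flicker — so trace statistics test the
estimator, not instrument pathology.

## The synthetic data: what it does and does not show

Every generator draws seeded Gaussian noise (σ = `noise_level`·√I for
scattering — a counting-statistics surrogate — and relative to peak height
or trace mean otherwise) and stores its full parameter set in the output
metadata; equal seeds are bit-identical. The generators reproduce the
*statistical structure* of the measurements: lineshapes, backgrounds,
resolution smearing, noise scaling. They do not simulate multiple
scattering, multilamellar structure-factor effects (Caillé lineshapes),
detector geometry, DSC scan-rate kinetics, or fluorescence lifetime
physics. Passing round-trip tests therefore demonstrates that the analysis
stages recover what the models put in, at the reported precision — it does
not validate the models against a real instrument.

## Problem sizes and defaults

The workflow and tests use 400-point log-spaced SANS curves over
0.05–5 nm⁻¹, ~1500-point SAXS/WAXS patterns, 761-point thermograms
(2–40 °C at 0.05 °C) and 241-sample traces (120 s at 0.5 s), with
Monte-Carlo property checks at 100 seeds — comfortably the scale of the
real experiments, and each stage runs in milliseconds. Default noise levels
(1–2% relative for scattering and traces, 0.2% of peak height for
calorimetry) reflect synchrotron/reactor count rates, a modern
low-volume calorimeter and a photon-counting fluorimeter.

## Known limitations

* The Kratky–Porod window convention exceeds the Guinier validity for
  ~4 nm bilayers (q·R~g~ up to ~1.28); the diagnostic is reported, and the
  slab oracle quantifies the model bias, but thickness values carry that
  systematic component just as published ones do.
* The 14.8/14.9 nm⁻¹ crystalline doublet is only resolvable when the
  linewidths are below the 0.1 nm⁻¹ separation; merged detections are
  flagged, not split.
* Absolute intensity calibration is out of scope throughout ("relative
  units"); only ratios and positions are quantitative.
* The low-dose composition figure is reported inconsistently at its source
  (0.05 vs 0.5 wt% for ~1:100 drug:lipid); `analysis/06_composition.R`
  tabulates both conversions (1:1130 and 1:113) without choosing.
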