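Package: surfbiophys
Title: Biophysical Characterisation of Drug-Loaded Lung-Surfactant Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for the thermodynamic and
    structural characterisation of lipid bilayers in exogenous pulmonary
    surfactant preparations carrying a hydrophobic drug. Infers bilayer
    thickness from small-angle neutron scattering curves via Kratky-Porod
    regression, lamellar repeat distance from small-angle X-ray diffraction
    peaks (Lorentzian fits), gel-to-fluid transition parameters (Tm, enthalpy,
    width) from differential scanning calorimetry thermograms, and the
    lateral-pressure parameter from pyrene excimer/monomer fluorescence.
    Includes seeded synthetic-data generators with known ground truth for
    every modality, so each analysis stage is verifiable by parameter
    recovery, plus composition arithmetic (weight percent to molar ratio) and
    an end-to-end simulate-analyse-report driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
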