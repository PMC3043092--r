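Package: stabfit
Title: Conformational Stability and Hydrodynamics of Proteins from
    Denaturation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise protein conformational stability and
    hydrodynamic behaviour from spectroscopic and calorimetric data.
    Turns fluorescence emission spectra into intensity-weighted average
    emission wavelengths, fits chemical denaturation curves with the
    linear extrapolation model (two- and three-state), thermal
    denaturation curves with the Gibbs-Helmholtz equation, differential
    scanning calorimetry endotherms (van't Hoff versus calorimetric
    enthalpy), and pH titrations (single and bell-shaped double pKa).
    Calibrates size-exclusion columns with the inverse-complementary-
    error-function partition-coefficient relationship and estimates
    Stokes radii, sphere radii, NMR rotational correlation times and
    molecular weights. Predicts theoretical m-values from changes in
    accessible surface area. Includes seeded synthetic-data generators
    for every input class so all fitting stages are testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
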