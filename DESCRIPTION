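Package: spectrangle
Title: Evaluation of MS/MS Fragment Intensity Predictions Against
    Experimental Spectra
Version: 0.1.0
Authors@R:
    person("spectrangle", "developers", email = "spectrangle@example.org",
           role = c("aut", "cre"))
Description: Tools to assess peptide MS/MS fragment-intensity predictors
    against experimental spectra. Annotates singly- and doubly-charged b/y
    fragment intensities from MGF spectra using ppm or Dalton matching
    tolerances, computes per-PSM similarity between predicted and
    experimental intensity vectors (normalized spectral angle and Pearson
    correlation), aggregates scores into precursor-weighted binned
    distributions, compares them to an experimental-reproducibility
    reference distribution via quantiles and the Wasserstein (earth
    mover's) distance, and ranks prediction methods overall and stratified
    by precursor charge, peptide length, collision energy and modification
    status. A seedable synthetic-data module simulates ground-truth
    fragmentation profiles, noisy experimental replicates and predictors
    of controlled accuracy so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
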