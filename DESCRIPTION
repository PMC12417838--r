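Package: ecogmap
Title: Spectral and Connectivity Mapping of Glioma Cortical Compartments from Intraoperative ECoG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate tumoral, close-peritumoral, far-peritumoral
    and healthy cortex from intraoperative electrocorticography (ECoG).
    Implements zero-phase Chebyshev II preprocessing, Welch power spectra with
    line-noise exclusion, absolute and relative canonical band powers with
    per-patient normalization, aperiodic (1/f) spectral parameterization into
    offset and exponent over multiple frequency ranges, phase-locking-value
    connectivity, Kruskal-Wallis and Dunn group statistics, Spearman
    correlation of spectral features with quantified tumor-cell infiltration,
    and compartment classification with a random-subspace kNN ensemble and a
    cubic-kernel SVM. A synthetic-recording generator with known ground truth
    (per-compartment colored-noise backgrounds, band-limited oscillations,
    line noise, phase-coupled channel groups and infiltration tables) makes
    the full pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    class,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
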