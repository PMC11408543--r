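Package: clsmr
Title: Connectome-Based Lesion-Symptom Mapping with Permutation Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for connectome-based lesion-symptom mapping (CLSM):
    quantification of lesion-induced structural disconnection from a
    streamline tractography atlas and patient lesion masks, extraction of
    behavioral symptoms (Go/NoGo performance index, signal-detection d'
    with the log-linear correction) and electrophysiological symptoms
    (N2/P3 global field power amplitudes over data-defined periods of
    interest), and a mass-univariate general linear model relating edge-wise
    disconnection severity to each symptom with family-wise error control by
    maximal-statistic permutation. Includes a synthetic phantom-brain,
    lesion-cohort, behavior and EEG generator with known ground-truth
    tract-symptom effects, so the whole pipeline can be exercised and
    validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
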