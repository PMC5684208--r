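Package: neuromodal
Title: Multi-Modal Analysis of Entorhinal Cortex Hyperactivity in Mouse Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of the quantitative
    pipeline used to characterise entorhinal-cortex hyperactivity in APOE4
    mouse models across five data modalities: contrast-enhanced cerebral
    blood volume (CBV) mapping with cluster-extent Monte-Carlo correction;
    speed-filtered local field potential (LFP) band-power analysis;
    spike-waveform-width classification of sorted units with firing-rate
    comparisons; in vitro event analysis (spontaneous extracellular field
    potentials, fEPSP slope and long-term potentiation time courses,
    template-matched miniature IPSC detection, and dF/F calcium transients);
    and targeted/untargeted LC-MS metabolomics differential abundance with
    Benjamini-Hochberg FDR control. A synthetic-data module generates every
    input modality with planted, recoverable ground truth so the whole
    pipeline can be exercised and validated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
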