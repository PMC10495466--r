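Package: corstate
Title: Cortical State Analysis for Intracranial Field Potential Recordings
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates trial-by-trial cortical state from intracranial field
    potential (ECoG) recordings through the pre-stimulus low (2.5-12 Hz) to
    high (12-80 Hz) frequency power ratio, and relates it to perceptual
    behavior. Provides zero-phase Chebyshev Type II band-pass and line-noise
    filtering implemented as second-order sections, common-average
    referencing, threshold-based epileptiform trial rejection, multitaper
    z-scored spectra and spectrograms, median-split state labelling,
    same-state probability with a trial-shuffle null, state-conditioned
    performance and reaction-time analyses, evoked-response coupling, and a
    cross-validated Fisher linear discriminant decoder of trial outcome.
    Includes a calibrated multi-electrode synthetic session generator with a
    shared latent state so that every pipeline stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), MASS, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
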