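Package: maskmvpa
Title: Multivariate Decoding and Representational Analysis for Backward-Masking EEG/fMRI Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for isolating recurrent visual processing with
    multivariate pattern analysis: pairwise linear-SVM decoding of EEG and fMRI
    data within and across backward-masking conditions, temporal generalization,
    Morlet time-frequency (power and phase) decoding, searchlight mapping,
    voxel-wise HRF-selection GLMs, representational similarity analysis with
    noise ceilings and commonality (shared-variance) partitioning, and the full
    resampling statistics (sign-permutation tests, cluster-based correction in
    one to three dimensions, FDR, bootstrap peak confidence intervals, paired
    peak-shift tests with Hedges' g). A synthetic-data generator emulates the
    study design (object conditions crossed with early/late masking, trial
    counts, channel montage, fMRI runs and ROIs, layered model RDMs) so that
    every stage is verifiable without real recordings. Includes a genetic
    algorithm for stimulus-subset selection that decorrelates two reference
    representational dissimilarity matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
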