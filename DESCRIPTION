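Package: pfmodes
Title: Probabilistic Functional Modes for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian matrix factorisation of multi-subject,
    multi-run resting-state fMRI into probabilistic functional modes (PFMs).
    Each mode is the outer product of a subject-specific spatial map and a
    run-specific time course; subject maps follow a voxelwise delta-Gaussian
    mixture beneath a group-level spike-and-slab hierarchy, and time courses
    carry a haemodynamic-response-function autocorrelation prior. Inference is
    conjugate-exponential variational Bayes with a monotone evidence lower
    bound. Includes a ground-truth simulator for parcel-based multi-subject
    rfMRI data, a decomposition scoring suite (uncentered correlation,
    Hungarian mode matching, netmat RMSE, test-retest reliability, Fisher-z
    group statistics, partial correlations, dual regression), and NIfTI/JSON
    input-output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
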