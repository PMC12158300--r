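Package: pndamm
Title: Process-Noise Dynamic Adaptation for Mesoscale EEG Network States
Version: 0.1.0
Authors@R: person("PNDA", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models neurofeedback training (NFT) as a discrete linear
    dynamical system over EEG correlation-network states. Provides a
    synthetic-data generator (network-level chains and signal-level
    VAR-coupled EEG), a seven-channel harmonization pipeline (resampling,
    zero-phase Butterworth filtering, common average reference, ICA-based
    artifact removal, segmentation, baseline correction, z-scoring),
    Spearman subnetwork and mesoscale network construction, per-session
    estimation of brain-state transition matrices with adaptive
    process-noise removal and cross-session alignment, a small CNN
    classifier of NFT versus resting states with leakage-free
    session-level splits, and mass-univariate weight statistics with
    Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
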