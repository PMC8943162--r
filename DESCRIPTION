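Package: channelmi
Title: Gaussian Mutual-Information Coupling, Pocket-State and Pore-Radius
    Analysis for Ion-Channel MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trajectory-analysis toolkit for studying allosteric coupling in
    ion channels such as TRPA1. Computes quasi-harmonic (Gaussian)
    configurational entropies and residue-pair mutual information from
    heavy-atom coordinate covariances, aggregates coupling maxima over
    replicate runs and monomers into pathway summaries, quantifies
    binding-pocket open/closed occupancy from Calpha-Calpha width series,
    and profiles channel pore radii with a probe-sphere slice optimizer.
    Ships a synthetic-trajectory generator (Gaussian fluctuations with
    prescribed covariance, Markov-switching pocket widths, toy pore
    geometries, rigid-motion frames) whose closed-form ground truths act as
    analytic oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
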