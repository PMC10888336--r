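Package: gelfun
Title: Mechano-Functional Characterization of Neuronal Networks Grown in Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize three-dimensional neuronal cultures grown in
    soft hydrogel scaffolds, combining small-amplitude oscillatory shear (SAOS)
    rheology with a network-based functional analysis of calcium-imaging
    recordings. The rheology side reduces time, strain and frequency sweep
    tables to storage/loss moduli, detects transients and low-frequency
    plateaus, converts the complex shear modulus to a Young's modulus, and
    compares developmental stages. The functional side normalizes fluorescence
    traces, detects activity events with a hysteretic Schmitt trigger, computes
    population activity and firing rates, infers directed effective
    connectivity with a binned transfer-entropy estimator and a pooled z-score
    significance rule, and summarizes the resulting graphs (average
    connectivity, global efficiency, Louvain modularity). A seeded synthetic
    data generator emulates the full experiment (ground-truth networks,
    stochastic cascade spiking, GCaMP6s-like fluorescence, rendered frame
    stacks, and rheological sweeps) so every stage can be validated against a
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
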