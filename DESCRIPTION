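Package: tpmkin
Title: Single-Molecule TPM Kinetics of Site-Specific Recombination
Version: 0.1.0
Authors@R:
    person("TPM", "Kinetics Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference tools for single-molecule tethered
    particle motion (TPM) studies of tyrosine-recombinase site-specific
    recombination (Cre-loxP, Flp-FRT). Provides an exact stochastic
    (Gillespie) simulator of the recombination pathway (non-productive,
    pre-synaptic, wayward and recombinogenic complexes), rendering of
    bead Brownian-motion amplitude time traces with an SDS-challenge end
    point, threshold-with-hysteresis state segmentation, dwell-time
    extraction with right censoring at the quench, single- and
    double-exponential dwell-time fitting (binned least squares and
    unbinned maximum likelihood), model selection, complex-census
    statistics normalized to the recombinase-bound fraction, and
    synapse-amplitude comparisons across target-site orientations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
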