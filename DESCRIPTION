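Package: pdzslots
Title: Competitive Binding Equilibria at PDZ-Domain Slots of PSD-95
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying competition among synaptic proteins for
    the three PDZ domains of the scaffold protein PSD-95. Implements
    competition-in-solution surface plasmon resonance (SPR) dissociation
    constant estimation with hyperbolic calibration-curve inversion,
    conventional equilibrium SPR and bead-saturation hyperbolic fits, a
    mass-action multi-ligand "slot" competition solver for modelling
    postsynaptic density (PSD) composition under phosphorylation and
    haploinsufficiency scenarios, immunoblot densitometry group statistics
    (Welch/pooled/paired one-tailed t-tests, Cohen's d, outlier screening),
    and seeded synthetic-data generators for end-to-end parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
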