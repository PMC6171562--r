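Package: mrmflux
Title: MRM Transition Design and Stable-Isotope Labeling Analysis for
    Central-Carbon Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational companion to a single-column LC-MS/MS method
    suite covering central-carbon, amino-acid and nucleotide metabolism.
    Provides molecular-formula mass arithmetic in nominal-integer and
    monoisotopic modes, including O-benzylhydroxylamine (OBHA) oxime
    derivatization stoichiometry; a machine-readable multiple-reaction-
    monitoring (MRM) transition library with a formula-based predictor
    and validator; generation of complete 13C/15N isotopologue transition
    ladders with fragment-aware label partitioning for moiety-resolved
    tracing; transparent chromatographic peak detection and trapezoidal
    integration with a synthetic-chromatogram generator; isotopologue-
    distribution analysis with binomial natural-abundance correction; and
    simulation and fitting of label-incorporation kinetics under
    first-order pool-turnover models for linear and cyclic pathway
    topologies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
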