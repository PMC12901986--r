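Package: collateralkit
Title: Simulation and Analysis of Cas13 Collateral RNA Cleavage Readouts
Version: 0.1.0
Authors@R: person("collateralkit", "maintainers", email = "maintainers@collateralkit.org", role = c("aut", "cre"))
Description: Tools for quantifying indiscriminate (collateral) RNA cleavage by
    target-activated Cas13 ribonucleoproteins in human cells. Implements
    electropherogram degradation quantification (total and regional AUC with
    total-AUC normalization), the 5'-3' RT-qPCR transcript-integrity dCq/ddCq
    statistic, ERCC-spike-in-anchored normalization with abundance-depletion
    regression and residual-threshold transcript selection, and long-read
    transcript-coverage dip detection with uracil cleavage-position assignment
    and sequence-context summaries. A molecule-level synthetic-data generator
    emulates the statistical structure of the corresponding experiments
    (activation kinetics, abundance-dependent depletion, spike-in immunity,
    US-dinucleotide cleavage preference, oligo-dT 3' bias) so that every
    analysis stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    withr
Config/testthat/edition: 3
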