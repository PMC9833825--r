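Package: dupdiv
Title: Simulation and Assays for Gene Duplication-Amplification-Divergence Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded stochastic serial-passage simulator for the joint
    dynamics of tandem-array copy-number mutations and adaptive promoter
    point mutations in bacterial populations, with a virtual dual-fluorophore
    (YFP/CFP) readout. Growth follows a saturating expression-fitness map in
    which gene-expression demand controls the sign of epistasis between
    dosage and promoter mutations, reproducing the regime in which frequent,
    reversible gene amplification hinders promoter divergence. Includes the
    accompanying measurement procedures: population- and single-cell
    fluorescence classification into ancestral/YFP+/YFP+CFP+/mixed fractions,
    steepest-sliding-window growth-rate estimation from OD time series,
    efficiency-corrected (Pfaffl) relative copy-number from qPCR Cq tables,
    and a 39-bp motif allele-fraction divergence metric for amplicon reads
    with contaminant exclusion. Synthetic-data generators emit plate-reader,
    flow-cytometry-like, amplicon FASTQ and qPCR files with known ground
    truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
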