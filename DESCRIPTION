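Package: polyrec
Title: Cation-Dependent DNA Polymerase Fidelity Landscapes from Deep Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for measuring how divalent
    cation concentrations modulate the misincorporation rate of error-prone
    DNA polymerases in barcoded primer-extension deep-sequencing assays.
    Generates fully-specified synthetic plates of paired-end reads with
    ground truth, filters and demultiplexes reads, aligns them to the
    error-free extension product, tallies misincorporations by position,
    template base and base transition, fits cation-to-error-rate transfer
    functions (gain, fold change, calcium responses), computes lag-one
    error coupling, Poisson overdispersion and sequence/structure binomial
    GLMs, and quantifies the Shannon information gain per base available
    for molecular recording of a binary cation state.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
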