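Package: foldkit
Title: Kinetic, Binding and Membrane Analysis for Outer-Membrane-Protein
    Folding Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tidy analysis tools for in vitro outer-membrane-protein (OMP)
    folding studies. Fits fluorescence folding transients with single- and
    double-exponential models under global (shared-rate) constraints,
    extracts t50 half-times from lag-phase transients, propagates errors
    through fold-change comparisons, fits Hill-equation binding curves from
    microscale thermophoresis titrations, computes gel-densitometry folded
    fractions and circular-dichroism mean residue ellipticity, and analyses
    coarse-grained bilayer snapshots for local versus bulk membrane
    thickness and acyl-chain order parameters around designated protein
    residues. Seeded synthetic-data generators produce folding transients,
    titrations, and bilayer trajectories with known ground truth so every
    stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
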