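Package: abpore
Title: Kinetics, Spectroscopy and Geometry of Amyloid-Beta(25-35) Membrane Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of calcium-permeable membrane pore
    formation by the amyloid-beta(25-35) peptide. Fits dye-influx
    (Quin-2) fluorescence traces with single-exponential and linearized
    second-order association models to extract pore-formation rate
    constants, in-membrane peptide affinity constants and oligomer
    numbers; decomposes polarized ATR-FTIR spectra into amide I and CH2
    band components to obtain secondary-structure fractions, dichroic
    ratios, lipid acyl-chain order parameters and beta-strand tilt
    angles; computes membrane-bound-peptide circular dichroism spectra
    by weighted subtraction; and evaluates closed-form beta-barrel pore
    geometry with van der Waals side-chain packing feasibility and
    ring-of-barrels supramolecular pore sizing. Includes seeded
    synthetic-data generators for every input so that all estimators
    can be validated by parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
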