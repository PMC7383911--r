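Package: silmtools
Title: Feasibility Planning and Analysis of Stable Isotopically Labeled
    Microdose Absolute Bioavailability Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative toolkit for planning and analysing absolute
    bioavailability trials that pair an oral therapeutic dose with a
    concomitant intravenous stable isotopically labeled microdose (SILM)
    quantified by LC-MS/MS. Computes aggregated (nominal mass shift)
    isotopologue abundance distributions of molecular formulas from
    elemental natural abundances, the maximum isotopic interference
    permitted by the 20% selectivity criterion, the minimum number of
    stable isotope labels per drug, the required assay lower limit of
    quantification from the three-half-life rule, and absolute
    bioavailability from paired labeled/unlabeled plasma
    concentration-time profiles by non-compartmental analysis. Includes
    a one-compartment pharmacokinetic simulator for the concomitant
    trial design, with multiplicative noise and an optional kinetic
    isotope effect, plus a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
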