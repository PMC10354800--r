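Package: nicospec
Title: Freebase Nicotine Fraction of E-Liquids from Non-Aqueous pH
    Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the freebase (fb) and monoprotonated (mp) nicotine
    fractions of e-cigarette liquids from a single non-aqueous pH reading and
    the dielectric constant of the propylene glycol / vegetable glycerin
    (PG/VG) solvent matrix.  Implements dielectric-constant-dependent linear
    calibrations of nicotine and benzoic acid pKa and of the solvent pH-scale
    offset delta, a Henderson-Hasselbalch-type speciation formula on the
    corrected pH scale, potentiometric titration analysis (first-derivative
    equivalence point, half-equivalence pKa, delta determination from
    strong-acid/strong-base titrations), Davies activity-coefficient
    utilities, and a charge-balance titration simulator so the whole analysis
    chain is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
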