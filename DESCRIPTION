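Package: aromatrace
Title: Wine Volatile Quantification, Odor Activity Profiling and
    Producing-Area Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for tracing the geographical origin of wines from their
    volatile compound profiles. Implements internal-standard calibration
    fitting and inversion with surrogate-curve assignment, temperature-
    programmed retention indices, odor activity values (OAV) and
    aroma-series intensities, orthogonal partial least squares discriminant
    analysis (OPLS-DA) with VIP scores, stratified cross-validated Q2 and
    permutation-test validation, one-way ANOVA with Tukey compact letter
    displays, and compound-climate Pearson correlation. Ships transcribed
    reference tables from a 26-winery, five-region Cabernet Sauvignon study
    and a synthetic-data generator emulating that design with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), mixOmics, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
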