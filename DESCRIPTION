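Package: mixrsm
Title: Mixture-Design Response Surface Analysis for Formulation Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing, fitting and optimizing mixture experiments
    on the composition simplex, motivated by essential-oil nanoemulsion
    formulation studies. Provides I-optimal design construction by point
    exchange, Scheffe mixture-polynomial fitting with response transforms,
    mixture ANOVA with Type I linear-mixture sums of squares and a
    lack-of-fit / pure-error split, backward model reduction, and
    Derringer-Suich desirability optimization over the simplex. Includes
    closed-form formulation metrics (Sauter mean diameter, DPPH inhibition
    and IC50 interpolation, droplet growth ratio, FICI synergy index), a
    synthetic-data generator for mixture studies, and a bundled 17-run
    three-oil nanoemulsion dataset for worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
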