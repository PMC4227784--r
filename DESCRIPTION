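Package: magscan
Title: Magnesium-Dependent Translational Control by Upstream Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying magnesium-dependent translational control
    exerted by upstream open reading frames (uORFs) in mRNA 5'-leaders.
    Annotates upstream AUGs, uORF geometry and Kozak initiation contexts in a
    5'-leader; implements a quantitative leaky-scanning/reinitiation model of
    cap-dependent 43S loading and start-codon selection as a function of added
    Mg2+ and K+, with a closed-form branching flux, a Monte-Carlo twin,
    construct mutation operators and joint parameter fitting; converts
    plate-reader luminescence kinetics into maximal synthesis rates; fits
    bell-shaped rate-versus-Mg2+ response curves and extracts magnesium optima,
    with extract calibration and reference normalisation; and generates fully
    synthetic in vitro translation datasets (leader fixtures and kinetic
    traces) so that the entire pipeline runs and is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
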