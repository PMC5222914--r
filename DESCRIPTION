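Package: dissokin
Title: Dissolution Profile Stability Analysis with DE, MDT and the Similarity Factor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing cumulative in-vitro drug-release profiles of
    controlled-release matrix tablets across accelerated-storage conditions.
    Implements the three standard model-independent dissolution statistics --
    dissolution efficiency (DE), mean dissolution time (MDT) and the
    regulatory similarity factor (f2) -- together with power-law
    (Korsmeyer-Peppas) release-kinetics simulation and fitting, a seeded
    generator of complete synthetic stability studies with a factorial
    drug x polymer-grade x storage-time design, and an end-to-end pipeline
    that reports per-arm metrics and f2-versus-fresh verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
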