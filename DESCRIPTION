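Package: paleorange
Title: Epoch-Stratified Ancestral Range Reconstruction and Paleoclimate
    Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood inference of geographic range evolution on
    time-calibrated phylogenies that may contain fossil tips.  Implements the
    Dispersal-Extinction-Cladogenesis (DEC) and BAYAREALIKE models with an
    optional founder-event (+J) cladogenetic component, time-stratified
    dispersal multiplier matrices encoding land-bridge history, AICc model
    comparison, marginal ancestral range reconstruction, deterministic
    extraction of dispersal/vicariance/extinction events with
    intercontinental versus adjacent scopes, lineage-through-time curves,
    and a paleoclimate correlation statistic that regresses event density on
    the absolute slope of a loess-smoothed deep-sea temperature curve.
    Includes forward simulators for birth-death chronograms, range histories
    with ground-truth event logs, and temperature series, so the whole
    pipeline is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
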