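Package: lacferm
Title: Kinetic Modelling of pH-Regulated Lactic Acid Production by
    Lactobacillus bulgaricus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Kinetic ordinary-differential-equation model of batch lactose
    fermentation by Lactobacillus delbrueckii subsp. bulgaricus, coupling
    Michaelis-Menten lactose metabolism, Monod growth with lactic-acid
    product inhibition, and transcriptional regulation of the lacSZ operon
    by a LacR repressor driven from a pH-induced promoter. Provides batch
    simulation of engineered and wild-type variants, calibration of the
    lacSZ basal transcription rate and of the milk pH-buffering curve,
    local (finite-difference) and Sobol (variance-based) parameter
    sensitivity analysis, two-level promoter/RBS scenario studies, and
    synthetic-data generators for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
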