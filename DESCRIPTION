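Package: evpsubtype
Title: Size-Resolved Single-Particle Profiling and Classification of
    Extracellular Vesicle Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-particle interferometric imaging of
    extracellular vesicles and particles (EVPs): detection of individual
    particle-landing events in image stacks, intensity-to-diameter
    calibration on silica beads with refractive-index compensation,
    size-resolved cumulative binding curves with saturating-exponential
    (Langmuir) kinetic fits, assembly of marker-by-size feature matrices,
    linear discriminant classification with cross-validation and
    one-vs-rest ROC analysis, and hill-climbing optimization of the size
    partition used for subtyping.  Includes a synthetic-data generator
    that emulates a five-class, five-marker EVP profiling experiment with
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
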