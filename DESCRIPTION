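Package: swathAnnotator
Title: Library-Guided Annotation of SWATH (DIA) Metabolomics Runs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Curates MS/MS spectral libraries into a DIA transition database,
    screens SWATH-acquired LC-MS runs for precursor candidates against that
    database, aligns fragment extracted-ion chromatograms with their precursor
    inside the precursor's SWATH isolation window using relative retention-time
    and peak-width shift criteria, and scores and validates the resulting
    identifications with inclusion/exclusion confusion statistics. A synthetic
    SWATH/IDA run generator provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
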