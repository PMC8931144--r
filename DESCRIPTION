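Package: biocnet
Title: Biocultural Values Networks from Coded Interview Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds directed, weighted co-occurrence networks linking
    cultural values and biophysical elements from coded interview
    segments, extracts the core network of strongest links by
    thresholding, and quantifies direct and cascading vulnerability of
    values to loss of biophysical elements through ego networks, k-step
    reachability and path-length summaries. Includes a seeded synthetic
    corpus generator with a planted core for end-to-end validation, and
    a command-line pipeline with deterministic GraphML, CSV and JSON
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    readr,
    rlang,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
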