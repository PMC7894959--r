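Package: endemica
Title: Integrated Conservation Assessment for Narrow-Endemic Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated conservation-assessment toolkit for small,
    fragmented plant populations, built around the monitoring of the
    Zakynthos cliff endemic Asperula naufraga. Provides range geometry
    (extent of occurrence by minimum convex polygon, area of occupancy by
    occupied grid cells), demographic and reproductive monitoring
    statistics, codominant SSR genetic-diversity and structure analysis
    (F-statistics, AMOVA with permutation tests, EM estimation of null
    alleles with ENA-corrected FST, Nei distances, PCoA, Evanno delta-K),
    a stochastic scalar population viability analysis, an IUCN Red List
    criterion-B/D/E rule engine, and a synthetic-data generator that
    emulates the statistical structure of every input so the whole
    pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    geosphere,
    vegan
Config/testthat/edition: 3
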