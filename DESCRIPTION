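Package: gwcqtl
Title: QTL Mapping and Sequential Fine-Mapping of Maize Grain Water Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting grain water content (GWC) and grain
    dehydration rate (GDR) in biparental maize populations.  Includes a
    synthetic-population generator (recombinant inbred lines and
    backcross-derived progenies with a known quantitative trait locus),
    trait computation from kernel fresh/dry weights, marker quality
    control and Kosambi genetic distances, interval and composite
    interval mapping with permutation-based LOD thresholds, ANOVA
    variance components with broad-sense heritability and
    multi-environment BLUP, and a sequential fine-mapping engine that
    narrows a QTL interval using recombinant-derived progeny tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
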