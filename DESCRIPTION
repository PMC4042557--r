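Package: cnvsweep
Title: CNV Discovery and Selective-Sweep Scanning in Diverging Wild Mouse Populations
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Run-based copy-number variant (CNV) calling from probe-level
    array-CGH log2 ratios (consecutive-probe threshold rule with a
    probe-density filter), cross-sample locus clustering and
    population-differentiation testing via a one-tailed hypergeometric
    test, genic feature-overlap annotation under a fraction-of-CNV rule,
    CNV-expression association statistics (Spearman correlation, Fisher
    enrichment, direction-concordance binomial test), and a microsatellite
    lnRH selective-sweep scan standardized against a neutral panel.
    Includes a deterministic synthetic-data generator producing probe
    tracks with known CNV truth sets, gene models, expression statistics
    and diploid microsatellite genotypes with optional sweep signatures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
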