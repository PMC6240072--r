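Package: fluxda
Title: Differential Flux Balance Analysis and Pathway Enrichment for
    Metabolic Reprogramming Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting metabolic reprogramming between two
    conditions of a constraint-based metabolic model and the matching
    metabolomics readouts. Implements flux balance analysis with
    parsimonious canonicalisation, differential flux analysis across a
    sweep of metabolic objectives, the per-pathway Differential Abundance
    score, KEGG-pathway based enrichment of ranked metabolite lists with
    permutation p-values (a weighted Kolmogorov-Smirnov-like statistic),
    paired-design differential metabolomics (litter-matched paired t-tests,
    fold changes, volcano classification), and stable-isotope tracer
    arithmetic (mass-isotopologue distributions, natural-abundance
    correction, consumption/release rates). Ships a curated synthetic
    central-carbon toy network and simulators for paired metabolomics so
    the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
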