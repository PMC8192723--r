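Package: commvade
Title: Whole-Community Invasion Analysis for Methanogenic Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-community (coalescence) invasion
    experiments in anaerobic digestion microbiomes. Attributes amplicon
    sequence variants (ASVs) in invaded communities to their resident or
    invader source community by endpoint presence, computes invasion-success
    statistics with worst-case bounds, implements first-principles weighted
    and unweighted UniFrac, distance-based permutational MANOVA with pairwise
    contrasts, a tipping-point taxon screen, and many-to-one (Dunnett-style)
    comparisons of biogas production against pure-community controls. A
    serial-transfer Wright-Fisher simulator with volumetric invasion doses,
    multinomial bottlenecks, sequencing-depth read sampling and a
    key-taxon-gated biogas model generates ground-truth-labelled synthetic
    studies so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    biomformat,
    vegan,
    phyloseq,
    multcomp,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
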