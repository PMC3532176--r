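Package: orthoscreen
Title: Cross-Species Screen for Conserved Stage-Dependent Gene Expression
    in Ovarian Follicular Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies ortholog groups whose member genes show concordant
    (same-direction) differential expression in the somatic cells
    surrounding the oocyte across three stages of developmental-competence
    acquisition (NC1, C1, C2), in up to four vertebrate species.  Provides
    the full analysis chain: presence filtering and median scale
    normalization of microarray intensities, one-way ANOVA with
    Benjamini-Hochberg correction and per-stage-pair direction calls,
    probe-to-gene homology mapping, OrthoMCL-style ortholog group inference
    (reciprocal best hits, in-paralogs, normalized similarity graph, Markov
    clustering), the cross-species concordance screen with subset sweeps,
    stage-profile clustering, and Fisher exact term enrichment.  A
    synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    igraph,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
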