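Package: perturbmap
Title: Building and Benchmarking Perturbative Maps from Genome-Scale
    Perturbation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maps@example.org",
           role = c("aut", "cre"))
Description: Tools for turning unit-level readouts of genome-scale
    perturbation screens (wells, cells) into perturbative maps: embed
    (PCA), filter (QC rules), align (control-anchored centering/scaling
    and typical-variation normalization with per-batch correlation
    alignment), aggregate (grouped means), and relate (cosine
    similarity).  Includes perturbation-signal benchmarks (replicate
    consistency, energy-distance magnitude, permutation p-values against
    an unexpressed-gene null), biological-relationship benchmarks
    (percentile-tail recall against annotated gene pairs,
    Kolmogorov-Smirnov protein-complex identification, hypergeometric
    gene-set enrichment), a replicate-subsampling noise-sensitivity
    analysis, and a synthetic-screen generator with known ground truth
    for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
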