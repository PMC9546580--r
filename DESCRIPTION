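Package: graviqtl
Title: Time-Resolved QTL Mapping and Cross-Species Orthology Filtering
    for Root Gravitropism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps quantitative trait loci (QTL) for root gravitropism in
    recombinant inbred line (RIL) populations from time-resolved root
    tip-angle phenotypes.  Includes a classical image-analysis pipeline
    (segmentation, skeletonization, tip-angle measurement), logistic and
    Gompertz response-curve fitting with extraction of the lag (lambda),
    maximal slope (mu), asymptote (A), spline peak (P), overshoot (P-A)
    and integral (I) parameters, hidden-Markov genotype probabilities,
    Haley-Knott single-QTL scans, permutation significance thresholds,
    penalized-LOD stepwise multiple-QTL models, per-time-point (tQTL)
    and per-parameter (pQTL) maps with track linking and matching, and a
    reciprocal-best-hit protein orthology filter that intersects QTL
    intervals between two species.  A synthetic-data module generates
    every input the pipeline consumes, with recorded ground truth, so
    the whole analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    EBImage,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
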