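Package: chipmeta
Title: Model-Based Meta-Analysis of ChIP-chip and ChIP-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative peak detection across heterogeneous chromatin
    immunoprecipitation experiments. Tiling-array (ChIP-chip) score tracks
    from different platforms are interpolated to a common genomic grid,
    normalized to Z-scores against a robustly estimated null, and combined
    by Stouffer's method; enriched regions are called on the composite score
    and an empirical false discovery rate is estimated by sign flipping.
    Sequencing (ChIP-seq) tag libraries from different laboratories are
    combined by estimating the characteristic ChIP-DNA fragment size of each
    library from the bimodal Watson/Crick tag pattern, shifting tags by half
    the fragment size, pooling, and scanning with a dynamic-lambda Poisson
    model; the empirical false discovery rate is estimated by swapping ChIP
    and control. Comparison baselines (majority voting, region intersection,
    merge-then-model), ROC and summit-accuracy evaluation, position weight
    matrix scanning against a Markov background, and synthetic spike-in and
    tag-library generators are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
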