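Package: regload
Title: Regulatory Load Scoring and Disease-Gene Enrichment from Enhancer Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-gene regulatory load (distinct transcription-factor
    count or active-enhancer peak count) from ChIP-Seq peak files by assigning
    peaks to GREAT-style 'BasalPlusExtension' regulatory domains, bins genes by
    load into tie-consistent deciles, and tests each bin for disease-gene
    enrichment with the hypergeometric distribution and Benjamini-Hochberg
    correction. Downstream analyses include cross-sample Jaccard similarity of
    high-load gene sets, cell-type-specific high-load genes, a resampling test
    for pathway occurrence, betweenness centrality in disease gene networks,
    and 3' UTR length / microRNA binding-site comparisons. A synthetic-data
    generator emulates the statistical structure of consortium epigenome
    inputs so the full pipeline runs and is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
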