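# regload

Regulatory load scoring and disease-gene enrichment from enhancer maps.

Genes controlled by many transcription factors — or, equivalently, flanked
by many active enhancers — are disproportionately disease-associated, and
the effect is cell-type-selective. `regload` implements the full analysis
for anyone with ChIP-Seq peak files and a gene annotation:

1. **Regulatory domains** — each gene gets a strand-aware basal window
   (5 kb up / 1 kb down of the TSS) extended up to 1 Mb but bounded by the
   neighboring genes' basal windows (the GREAT "BasalPlusExtension" rule).
2. **Loads** — TF load = number of distinct TFs with a peak contained in
   the domain; enhancer load = count of H3K27ac peaks contained in it.
   Genes without an H3K4me3 peak within TSS ± 1 kb ("closed" genes) are
   excluded from testing.
3. **Binning** — open genes are ranked by load and cut into deciles, each
   bin absorbing all genes that tie with its last member, plus a separate
   zero-load bin.
4. **Enrichment** — every (sample, disease, bin) cell is tested with the
   inclusive hypergeometric upper tail
   `p = P(X >= k), X ~ Hypergeom(N, K, n)` (N = open genes, K = open
   disease genes, n = bin size, k = disease genes in the bin), BH-adjusted,
   and optionally binarized at -log10 p = 1.301.
5. **Downstream** — cross-sample Jaccard similarity of top bins,
   cell-type-specific high-load genes, a 10 000-fold resampling test for
   KEGG-style pathway occurrence, betweenness centrality
   `B(v) = sum_{s != v != t} d(s,v,t)/d(s,t)` in a one-step disease gene
   network, and one-sided Kolmogorov-Smirnov comparisons of 3' UTR lengths
   with deduplicated miRNA target-site counts.

A synthetic-data module (`simulate_study()`) generates every input with the
statistical structure the analysis assumes — correlated TF/enhancer loads,
a planted disease-gene excess in the top load decile, load-biased pathway
and network membership, longer 3' UTRs for high-load genes — so the whole
pipeline runs and is testable without any downloads.

## Worked example

```r
library(regload)

sim <- simulate_study(sim_config(), seed = 1)   # 2000 genes, 4 samples
res <- run_pipeline(sim, seed = 1)

# recovery of the planted high-load genes by the top bin of sample 1
hrl <- res$top_bins$sample01
length(intersect(hrl, sim$truth$planted_hrl)) /
  length(union(hrl, sim$truth$planted_hrl))
#> [1] 0.993865

# top-bin disease enrichment (sample 1): fraction of diseases significant
top <- subset(res$enrichment, sample_id == "sample01" & bin_rank == 1)
mean(top$p_adj < 0.05)
#> [1] 0.7291667

# pathway occurrence: high-load genes sit in more pathways than random
# draws of open genes (10 000-fold resampling)
res$pathway_test$observed_mean        # 1.807018  pathways per HRL gene
mean(res$pathway_test$null_means)     # 1.485098  pathways per random gene
res$pathway_test$p                    # 9.999e-05

# betweenness centrality in the disease gene network: ~4.7x the null mean
res$network_test$observed_mean / mean(res$network_test$null_means)
#> [1] 4.680717

# 3' UTR lengths of high-load genes are stochastically larger
subset(res$utr_test, feature == "utr3_length")
#>       feature  mean_bg mean_test    D_plus           p significant
#>   utr3_length 1208.912   1625.08 0.1821626 4.52857e-05        TRUE
```

The numbers read exactly as in the full-scale analysis: the top decile of
enhancer load concentrates the planted disease genes, appears in ~1.3x more
pathways than chance, occupies the central nodes of the disease network,
and carries ~35% longer 3' UTRs with correspondingly more miRNA sites.

## Layout

- `R/io.R` — BED/narrowPeak, gene annotation, association table, GMT, edge
  list, enrichment matrix readers/writers (0-based half-open throughout)
- `R/domains.R` — regulatory domains, peak filtering, replicate consensus,
  open-gene calling, containment assignment
- `R/load.R` — TF/enhancer loads, tie-consistent decile binning, Jaccard,
  cell-type-specific sets, expression overlap
- `R/enrich.R` — disease sets, evidence partition, hypergeometric tail,
  BH families, binarization
- `R/network.R` — disease network, betweenness, resampling tests, pathway
  counts
- `R/utr.R` — one-sided KS, Bonferroni, miRNA site deduplication
- `R/simulate.R`, `R/pipeline.R` — synthetic study and end-to-end driver
- `vignettes/regulatory-load-methods.Rmd` — models, conventions, design
  decisions and limitations
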