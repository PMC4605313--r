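# End-to-end driver over an in-memory study (simulated or loaded).

#' Run the complete regulatory-load analysis
#'
#' For every sample: peak filtering is skipped for samples marked
#' unfiltered; open genes are called from the H3K4me3 peaks; H3K27ac peaks
#' are assigned to regulatory domains by containment; the per-gene enhancer
#' load is binned into tie-consistent deciles; each bin is tested for
#' disease-gene enrichment. Across samples, the pairwise Jaccard similarity
#' of the top bins is computed. For the first sample, the pathway
#' occurrence resampling test, the disease-network betweenness resampling
#' test and the 3' UTR length comparison are run on its high-load genes.
#'
#' @param study list as returned by [simulate_study()] (chrom_sizes, genes,
#'   domains, samples, associations, pathways, ppi_edges, transcripts,
#'   mirna_sites).
#' @param n_bins quantile bins before tie extension (default 10).
#' @param min_score,min_genes disease-set filters (defaults 0.08 / 15).
#' @param resamples resampling-null size (default 10000).
#' @param seed integer seed for the resampling draws.
#' @param apply_peak_filter filter peaks on fold change / q-value >= 3
#'   before assignment.
#' @return list with per-sample `open_sets`, `load_tables`, `partitions`,
#'   `top_bins`; `enrichment` (long table), `jaccard`, `disease_sets`,
#'   `pathway_test`, `network_test` (with `betweenness`), `utr_test`,
#'   `mirna_counts`.
#' @export
run_pipeline <- function(study, n_bins = 10, min_score = 0.08,
                         min_genes = 15, resamples = 10000, seed = 1L,
                         apply_peak_filter = FALSE) {
  genes <- study$genes
  domains <- study$domains
  if (is.null(domains)) {
    domains <- create_regulatory_domains(genes, study$chrom_sizes)
  }

  open_sets <- list(); load_tables <- list()
  partitions <- list(); top_bins <- list()
  for (sid in names(study$samples)) {
    s <- study$samples[[sid]]
    k4 <- s$h3k4me3; k27 <- s$h3k27ac
    if (apply_peak_filter) {
      k4 <- filter_peaks(k4); k27 <- filter_peaks(k27)
    }
    open <- open_genes(genes, list(k4))
    lt <- enhancer_load(assign_peaks(domains, k27), genes, open)
    part <- bin_by_load(lt, n_bins = n_bins)
    open_sets[[sid]] <- open
    load_tables[[sid]] <- lt
    partitions[[sid]] <- part
    top_bins[[sid]] <- top_bin(part)
  }

  disease_sets <- build_disease_sets(study$associations, genes$gene_id,
                                     min_score = min_score,
                                     min_genes = min_genes)
  cells <- enrich_matrix(partitions, disease_sets)
  jac <- jaccard_matrix(top_bins)

  s1 <- names(study$samples)[1]
  hrl <- top_bins[[s1]]
  open1 <- open_sets[[s1]]

  pw <- pathway_counts(study$pathways, open1)
  pw_target <- intersect(hrl, names(pw$counts))
  pathway_test <- resample_mean_stat(pw$counts, pw_target,
                                     intersect(open1, names(pw$counts)),
                                     R = resamples, seed = seed)
  pathway_test$background_mean <-
    pathway_counts(study$pathways, genes$gene_id)$mean

  seeds <- unique(unlist(disease_sets))
  net <- build_disease_network(seeds, study$ppi_edges)
  btw <- betweenness_centrality(net)
  pool <- intersect(igraph::V(net)$name, open1)
  network_test <- resample_mean_stat(btw, intersect(hrl, pool), pool,
                                     R = resamples, seed = seed + 1L)
  network_test$betweenness <- btw

  utr_test <- utr_length_test(study$transcripts, hrl)
  mirna_counts <- count_mirna_sites(study$mirna_sites)

  list(open_sets = open_sets, load_tables = load_tables,
       partitions = partitions, top_bins = top_bins,
       enrichment = cells, jaccard = jac, disease_sets = disease_sets,
       pathway_test = pathway_test, network_test = network_test,
       utr_test = utr_test, mirna_counts = mirna_counts)
}

#' Load a study from a directory written by [write_simulation()]
#'
#' Reads the annotation, per-sample peak files, association table,
#' pathways, PPI edges, transcript annotation and miRNA sites back into
#' the in-memory study structure consumed by [run_pipeline()].
#'
#' @param dir directory path.
#' @return study list (without domains; [run_pipeline()] rebuilds them).
#' @export
read_study <- function(dir) {
  fp <- function(...) file.path(dir, ...)
  chrom_sizes <- read_chrom_sizes(fp("chrom.sizes"))
  genes <- read_gene_annotation(fp("genes.tsv"))
  peak_files <- list.files(dir, pattern = "\\.narrowPeak$")
  sids <- unique(sub("_.*", "", peak_files))
  samples <- list()
  for (sid in sids) {
    mine <- peak_files[startsWith(peak_files, paste0(sid, "_"))]
    marks <- sub("\\.narrowPeak$", "", sub("^[^_]*_", "", mine))
    tf_files <- mine[grepl("^TF", marks)]
    tf_peaks <- lapply(tf_files, function(f) read_bed(fp(f), "peak_with_stats"))
    names(tf_peaks) <- sub("\\.narrowPeak$", "", sub("^[^_]*_", "", tf_files))
    samples[[sid]] <- list(
      sample_id = sid, cell_type = NA_character_,
      h3k4me3 = read_bed(fp(paste0(sid, "_H3K4me3.narrowPeak")),
                         "peak_with_stats"),
      h3k27ac = read_bed(fp(paste0(sid, "_H3K27ac.narrowPeak")),
                         "peak_with_stats"),
      tf_peaks = tf_peaks)
  }
  expr <- NULL
  if (file.exists(fp("expression.tsv"))) {
    etab <- read.delim(fp("expression.tsv"), check.names = FALSE)
    expr <- as.matrix(etab[, -1, drop = FALSE])
    rownames(expr) <- etab[[1]]
  }
  list(chrom_sizes = chrom_sizes, genes = genes, samples = samples,
       associations = read_associations(fp("associations.tsv")),
       pathways = read_gmt(fp("pathways.gmt")),
       ppi_edges = read_edge_list(fp("ppi.tsv")),
       transcripts = read.delim(fp("transcripts.tsv"),
                                stringsAsFactors = FALSE),
       mirna_sites = read.delim(fp("mirna_sites.tsv"),
                                stringsAsFactors = FALSE),
       expression = expr)
}
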