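# Disease gene network, betweenness centrality and resampling tests.

#' Build a one-step disease gene network
#'
#' Nodes are the seed (disease) genes present in the protein-protein
#' interaction (PPI) network plus all their direct interactors; edges are
#' ALL PPI edges with both endpoints in that node set (induced subgraph).
#' The graph is undirected and unweighted, with self-loops and duplicate
#' edges removed. Seed genes absent from the PPI are dropped with a
#' warning.
#'
#' @param seed_genes character vector of seed gene ids.
#' @param ppi_edges data.frame with columns `from`, `to`.
#' @return igraph object with a logical vertex attribute `seed`.
#' @export
build_disease_network <- function(seed_genes, ppi_edges) {
  edges <- normalize_edges(ppi_edges$from, ppi_edges$to)
  ppi_nodes <- unique(c(edges$from, edges$to))
  present <- intersect(seed_genes, ppi_nodes)
  if (length(present) == 0) stop("no seed gene present in the PPI network")
  missing <- setdiff(seed_genes, ppi_nodes)
  if (length(missing)) {
    warning(length(missing), " seed gene(s) absent from the PPI were dropped")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nbrs <- unique(unlist(lapply(igraph::adjacent_vertices(g, present), names)))
  nodes <- union(present, nbrs)
  sub <- igraph::induced_subgraph(g, nodes)
  igraph::V(sub)$seed <- igraph::V(sub)$name %in% present
  sub
}

#' Betweenness centrality (ordered-pair convention)
#'
#' For every node v, sums over all ordered pairs (s, t) with s != v != t
#' the fraction of shortest s-t paths passing through v; unreachable pairs
#' contribute 0. Each unordered pair is counted twice (once per direction)
#' and no normalization is applied, so the centre of a 3-node path scores 2
#' and the centre of a star with n nodes scores (n-1)(n-2).
#'
#' @param network igraph object (treated as undirected, unweighted).
#' @param normalized divide by (N-1)(N-2), the count of ordered pairs.
#' @return named numeric vector of centralities.
#' @export
betweenness_centrality <- function(network, normalized = FALSE) {
  # igraph reports each unordered pair once for undirected graphs; the
  # ordered-pair convention doubles it
  b <- 2 * igraph::betweenness(network, directed = FALSE, weights = NA)
  if (normalized) {
    N <- igraph::vcount(network)
    if (N > 2) b <- b / ((N - 1) * (N - 2))
  }
  b
}

#' Resampling test for the mean of a node/gene statistic
#'
#' Compares the observed mean of `values` over `target_set` against a null
#' of `R` random draws of `|target_set|` genes, sampled WITHOUT replacement
#' from `sampling_pool`. The p-value is the add-one estimator
#' (1 + #\{null means >= observed\}) / (R + 1), the probability to obtain at
#' least the same average by chance.
#'
#' @param values named numeric vector (e.g. betweenness per node, pathway
#'   count per gene). Genes of the target or pool absent from `values` are
#'   ignored in the respective means.
#' @param target_set character vector, subset of `sampling_pool`.
#' @param sampling_pool character vector of genes to draw from.
#' @param R number of resamples (default 10000).
#' @param seed integer seed for reproducibility.
#' @return list with `observed_mean`, `null_means` (length R), `p`.
#' @export
resample_mean_stat <- function(values, target_set, sampling_pool, R = 10000,
                               seed = 1L) {
  if (!all(target_set %in% sampling_pool)) {
    stop("target_set must be a subset of sampling_pool")
  }
  size <- length(target_set)
  if (size > length(sampling_pool)) stop("target larger than sampling pool")
  obs <- mean(values[intersect(target_set, names(values))])
  set.seed(seed)
  null_means <- vapply(seq_len(R), function(i) {
    draw <- sample(sampling_pool, size)
    mean(values[intersect(draw, names(values))])
  }, 0)
  p <- (1 + sum(null_means >= obs)) / (R + 1)
  list(observed_mean = obs, null_means = null_means, p = p)
}

#' Pathway occurrence counts per gene
#'
#' Counts, for each gene of `gene_set` that appears in at least one
#' pathway, the number of pathways containing it; genes absent from every
#' pathway are excluded from the mean's denominator (the "per pathway-gene"
#' convention).
#'
#' @param pathways named list of pathway gene sets (e.g. from
#'   [read_gmt()]).
#' @param gene_set character vector of genes to evaluate.
#' @return list with `counts` (named vector over gene_set intersected with
#'   the pathway universe) and `mean`.
#' @export
pathway_counts <- function(pathways, gene_set) {
  universe_counts <- table(unlist(lapply(pathways, unique)))
  present <- intersect(gene_set, names(universe_counts))
  if (length(present) == 0) {
    stop("gene_set is disjoint from the pathway universe")
  }
  counts <- setNames(as.numeric(universe_counts[present]), present)
  list(counts = counts, mean = mean(counts))
}
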