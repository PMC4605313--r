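# Independent brute-force oracles used across tests. These deliberately use
# naive O(n*m) scans and explicit enumeration so they share no code path
# with the implementation they check.

# all-pairs containment scan: peak assigned iff fully inside the domain
brute_assign <- function(domains, peaks) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(domains))) {
      if (peaks$chrom[i] == domains$chrom[j] &&
          domains$domain_start[j] <= peaks$start[i] &&
          peaks$end[i] <= domains$domain_end[j]) {
        out[[length(out) + 1]] <- data.frame(gene_id = domains$gene_id[j],
                                             peak_idx = i)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene_id = character(), peak_idx = integer()))
  }
  do.call(rbind, out)
}

# all-pairs >=1bp overlap scan of TSS windows against peaks
brute_open <- function(genes, peaks, window = 1000) {
  open <- character()
  for (i in seq_len(nrow(genes))) {
    ws <- max(genes$tss[i] - window, 0)
    we <- genes$tss[i] + window + 1
    for (j in seq_len(nrow(peaks))) {
      if (genes$chrom[i] == peaks$chrom[j] &&
          min(we, peaks$end[j]) - max(ws, peaks$start[j]) >= 1) {
        open <- c(open, genes$gene_id[i])
        break
      }
    }
  }
  open
}

# exact hypergeometric upper tail by pmf enumeration with choose()
enum_hyper_upper <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# hand step-up BH adjustment
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# ordered-pair betweenness by BFS shortest-path counting (sigma algebra),
# independent of igraph
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- d
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  b <- numeric(n)
  for (v in 1:n) {
    for (s in 1:n) {
      for (t in 1:n) {
        if (s == v || t == v || s == t) next
        if (is.finite(dist[s, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

# random gene/peak fixture on a 2-chromosome toy genome
random_fixture <- function(n_genes, n_peaks, seed) {
  set.seed(seed)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tss = sample(5000:995000, n_genes), stringsAsFactors = FALSE)
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  st <- sample(0:990000, n_peaks, replace = TRUE)
  peaks <- peak_table(sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
                      st, st + sample(200:5000, n_peaks, replace = TRUE))
  list(genes = genes, sizes = sizes, peaks = peaks)
}
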