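# Per-gene regulatory load, tie-consistent decile binning, and cross-sample
# set analyses.

#' Transcription-factor load per gene
#'
#' The TF load of a gene is the number of DISTINCT TFs with at least one
#' peak assigned to the gene's regulatory domain; multiple peaks of the same
#' TF count once. Genes outside the open set keep their load value but are
#' flagged closed.
#'
#' @param tf_assignments named list of `peak_assignment` objects, one per TF
#'   (names = TF identifiers, must be unique).
#' @param genes gene data.frame (defines the background and row order).
#' @param open_set character vector of open gene ids.
#' @return load table: data.frame gene_id, load, open; attribute
#'   `load_kind = "tf"`.
#' @export
tf_load <- function(tf_assignments, genes, open_set) {
  if (is.null(names(tf_assignments)) || anyDuplicated(names(tf_assignments))) {
    stop("tf_assignments must be a uniquely named list (one entry per TF)")
  }
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  for (tf in names(tf_assignments)) {
    g <- unique(tf_assignments[[tf]]$assignments$gene_id)
    g <- intersect(g, genes$gene_id)
    counts[g] <- counts[g] + 1L
  }
  out <- data.frame(gene_id = genes$gene_id, load = unname(counts),
                    open = genes$gene_id %in% open_set,
                    stringsAsFactors = FALSE)
  attr(out, "load_kind") <- "tf"
  out
}

#' Enhancer load per gene
#'
#' The enhancer load is the raw count of H3K27ac peak records assigned to
#' the gene's regulatory domain (records with identical coordinates count
#' separately).
#'
#' @param h3k27ac_assignment `peak_assignment` object for the H3K27ac peaks.
#' @param genes gene data.frame.
#' @param open_set character vector of open gene ids.
#' @return load table as in [tf_load()], `load_kind = "enhancer"`.
#' @export
enhancer_load <- function(h3k27ac_assignment, genes, open_set) {
  tab <- table(h3k27ac_assignment$assignments$gene_id)
  counts <- setNames(integer(nrow(genes)), genes$gene_id)
  common <- intersect(names(tab), genes$gene_id)
  counts[common] <- as.integer(tab[common])
  out <- data.frame(gene_id = genes$gene_id, load = unname(counts),
                    open = genes$gene_id %in% open_set,
                    stringsAsFactors = FALSE)
  attr(out, "load_kind") <- "enhancer"
  out
}

#' Bin genes by regulatory load into tie-consistent deciles
#'
#' Open genes with zero load form a separate zero-load bin. The remaining
#' genes are sorted by descending load and cut at ranks `ceiling(k * m /
#' n_bins)`; each bin is then extended downward to absorb ALL genes tying
#' with the load of its last member, the next bin starting after the
#' absorbed ties. Bins emptied by the absorption are dropped, so a sample
#' may end with fewer than `n_bins` bins. `bin_rank` 1 is the highest-load
#' bin.
#'
#' By default only open genes are binned (`filter_open_first = TRUE`), so the
#' bins partition the population used by the hypergeometric tests. With
#' `filter_open_first = FALSE` all genes are ranked and binned first, then
#' closed genes are removed from the resulting bins.
#'
#' @param load_table load table from [tf_load()] / [enhancer_load()].
#' @param n_bins number of quantile bins before tie extension (default 10).
#' @param filter_open_first bin only open genes (default) or bin all genes
#'   and drop closed ones afterwards.
#' @return object of class `bin_partition`: list with `bins` (list of lists
#'   with bin_rank, load_min, load_max, genes), `zero_bin` (gene ids),
#'   `population` (all binned gene ids incl. zero bin).
#' @export
bin_by_load <- function(load_table, n_bins = 10, filter_open_first = TRUE) {
  tab <- load_table
  if (filter_open_first) tab <- tab[tab$open, , drop = FALSE]
  if (nrow(tab) == 0) stop("no genes to bin (empty open set)")

  zero <- tab$gene_id[tab$load == 0]
  nz <- tab[tab$load > 0, , drop = FALSE]
  ord <- order(-nz$load, nz$gene_id)
  loads <- nz$load[ord]
  ids <- nz$gene_id[ord]
  m <- length(loads)

  bins <- list()
  start <- 1L
  if (m > 0) {
    for (k in seq_len(n_bins)) {
      end <- as.integer(ceiling(k * m / n_bins))
      if (end < start) next
      while (end < m && loads[end + 1L] == loads[end]) end <- end + 1L
      bins[[length(bins) + 1L]] <- list(
        bin_rank = length(bins) + 1L,
        load_min = loads[end], load_max = loads[start],
        genes = ids[start:end])
      start <- end + 1L
      if (start > m) break
    }
  }

  if (!filter_open_first) {
    open_ids <- load_table$gene_id[load_table$open]
    bins <- lapply(bins, function(b) {
      b$genes <- intersect(b$genes, open_ids)
      b
    })
    bins <- Filter(function(b) length(b$genes) > 0, bins)
    for (i in seq_along(bins)) bins[[i]]$bin_rank <- i
    zero <- intersect(zero, open_ids)
  }

  res <- list(bins = bins, zero_bin = zero,
              population = c(unlist(lapply(bins, `[[`, "genes")), zero))
  class(res) <- "bin_partition"
  validate_bin_partition(res)
  res
}

#' Validate the structural invariants of a bin partition
#'
#' Checks that the bins plus the zero bin partition the population, that
#' load ranges are ordered and disjoint across bins, and that no load value
#' appears in two bins (tie consistency).
#'
#' @param partition `bin_partition` object.
#' @return the partition, invisibly; errors on violation.
#' @export
validate_bin_partition <- function(partition) {
  all_genes <- c(unlist(lapply(partition$bins, `[[`, "genes")),
                 partition$zero_bin)
  if (anyDuplicated(all_genes)) stop("bins do not partition the population")
  if (!setequal(all_genes, partition$population)) {
    stop("bin membership does not match the recorded population")
  }
  if (length(partition$bins) > 1) {
    lo <- vapply(partition$bins, `[[`, 0, "load_min")
    hi <- vapply(partition$bins, `[[`, 0, "load_max")
    if (any(lo > hi)) stop("bin with load_min > load_max")
    # rank 1 = highest load; next bin's max must be strictly below this min
    if (any(hi[-1] >= lo[-length(lo)])) {
      stop("bin load ranges overlap or are out of order (tie inconsistency)")
    }
  }
  invisible(partition)
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("bin partition: %d load bins + zero bin (%d genes), %d genes total\n",
              length(x$bins), length(x$zero_bin), length(x$population)))
  for (b in x$bins) {
    cat(sprintf("  bin %d: load %s..%s, %d genes\n", b$bin_rank,
                b$load_min, b$load_max, length(b$genes)))
  }
  invisible(x)
}

#' Genes of the top (highest-load) bin
#'
#' Returns the gene set of bin rank 1. The zero-load bin is never the top
#' bin; a partition with only a zero bin is an error.
#'
#' @param partition `bin_partition` object.
#' @return character vector of gene ids (the high-regulatory-load genes).
#' @export
top_bin <- function(partition) {
  if (length(partition$bins) == 0) {
    stop("partition has no nonzero-load bins")
  }
  partition$bins[[1]]$genes
}

#' Pairwise Jaccard similarity of gene sets
#'
#' J(A, B) = |A intersect B| / |A union B|; J(empty, empty) is defined as 1.
#'
#' @param sets named list of character vectors (e.g. top bins per sample).
#' @return symmetric numeric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(sets) {
  n <- length(sets)
  mat <- matrix(1, n, n, dimnames = list(names(sets), names(sets)))
  if (n < 2) return(mat)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      u <- length(union(sets[[i]], sets[[j]]))
      mat[i, j] <- mat[j, i] <-
        if (u == 0) 1 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  mat
}

#' Cell-type-specific high-load genes
#'
#' The union of top bins over the target samples minus the union of top
#' bins over all other samples.
#'
#' @param top_bins named list of gene-id vectors, one per sample.
#' @param target_sample_ids sample names to combine.
#' @return character vector of target-specific gene ids.
#' @export
cell_type_specific <- function(top_bins, target_sample_ids) {
  if (!all(target_sample_ids %in% names(top_bins))) {
    stop("unknown target sample id(s): ",
         paste(setdiff(target_sample_ids, names(top_bins)), collapse = ", "))
  }
  targets <- unique(unlist(top_bins[target_sample_ids]))
  others <- unique(unlist(top_bins[setdiff(names(top_bins), target_sample_ids)]))
  setdiff(targets, others)
}

#' Overlap of high-load genes with top expression bins
#'
#' Ranks genes by descending expression and reports the cumulative
#' proportion of the high-regulatory-load (HRL) set found among the top
#' `|HRL|`, `3 |HRL|`, 50% and 90% most expressed genes; the 50%/90% cuts
#' are relative to the total number of genes with expression data.
#'
#' @param expression named numeric vector of expression values.
#' @param hrl_set character vector of high-load gene ids.
#' @return named numeric vector of the four cumulative proportions
#'   (top_hrl, top_3hrl, top_50pct, top_90pct), non-decreasing.
#' @export
expression_overlap <- function(expression, hrl_set) {
  total <- length(expression)
  h <- length(hrl_set)
  if (h > total) stop("more HRL genes than genes with expression data")
  ranked <- names(sort(expression, decreasing = TRUE))
  # cummax keeps the four cuts nested even when |HRL| is large
  sizes <- cummax(pmin(c(h, 3 * h, round(0.5 * total), round(0.9 * total)), total))
  props <- vapply(sizes, function(s) {
    length(intersect(hrl_set, ranked[seq_len(s)])) / h
  }, 0)
  setNames(props, c("top_hrl", "top_3hrl", "top_50pct", "top_90pct"))
}
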