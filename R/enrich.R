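# Disease gene sets and hypergeometric enrichment of load bins.

#' Build disease gene sets from an association table
#'
#' Per disease, keeps genes with association score >= `min_score`. The
#' `min_genes` threshold is applied to that gene count BEFORE intersection
#' with the background (`count_in_background = FALSE`, the default); the
#' surviving sets are then restricted to the background. With
#' `count_in_background = TRUE` the threshold is applied after the
#' intersection instead.
#'
#' @param associations association data.frame (gene_id, disease_id, score,
#'   evidence_types).
#' @param background character vector of background gene ids.
#' @param min_score minimum association score (default 0.08; 0.2 selects the
#'   curated tier).
#' @param min_genes minimum number of associated genes per disease
#'   (default 15).
#' @param count_in_background apply `min_genes` after background
#'   intersection.
#' @return named list of character vectors (disease id -> gene set,
#'   restricted to background).
#' @export
build_disease_sets <- function(associations, background, min_score = 0.08,
                               min_genes = 15, count_in_background = FALSE) {
  if (length(background) == 0) stop("empty background gene set")
  keep <- associations$score >= min_score
  sets <- split(associations$gene_id[keep], associations$disease_id[keep])
  sets <- lapply(sets, unique)
  if (!count_in_background) {
    sets <- sets[lengths(sets) >= min_genes]
    sets <- lapply(sets, intersect, background)
  } else {
    sets <- lapply(sets, intersect, background)
    sets <- sets[lengths(sets) >= min_genes]
  }
  sets
}

#' Partition background genes by disease-association evidence
#'
#' Splits the background into three disjoint sets: genes with at least one
#' qualifying (score >= `min_score`) association carrying the evidence type
#' 'genetic variation'; remaining disease genes ('other evidence':
#' altered expression, biomarker, post-translational modification,
#' therapeutic); and genes with no qualifying association at all.
#'
#' @param associations association data.frame.
#' @param background character vector of background gene ids.
#' @param min_score minimum qualifying score (default 0.08).
#' @return list with elements `genetic_variation`, `other_evidence`,
#'   `non_disease`; the three partition the background.
#' @export
partition_by_evidence <- function(associations, background, min_score = 0.08) {
  qual <- associations[associations$score >= min_score, , drop = FALSE]
  has_gv <- vapply(strsplit(qual$evidence_types, ";", fixed = TRUE),
                   function(x) "genetic variation" %in% x, TRUE)
  gv_genes <- intersect(unique(qual$gene_id[has_gv]), background)
  disease_genes <- intersect(unique(qual$gene_id), background)
  list(genetic_variation = gv_genes,
       other_evidence = setdiff(disease_genes, gv_genes),
       non_disease = setdiff(background, disease_genes))
}

#' Hypergeometric upper tail P(X >= k)
#'
#' Probability of observing at least `k` successes when drawing `n` items
#' without replacement from a population of `N` items of which `K` are
#' successes. Note this is the INCLUSIVE upper tail (1 - CDF(k - 1)), not
#' the cumulative distribution function itself; `k = 0` gives exactly 1.
#'
#' @param N population size.
#' @param K number of successes in the population.
#' @param n number of draws.
#' @param k observed number of successes.
#' @return p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k < 0 || k > min(K, n)) stop("k must lie in [0, min(K, n)]")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of disease genes across load bins
#'
#' For every sample, disease and bin: population size N = binned open
#' genes, successes K = disease genes in that population, draws n = bin
#' size, observed k = disease genes in the bin; p is the inclusive
#' hypergeometric upper tail. Benjamini-Hochberg adjustment is applied
#' within the family given by `bh_family`: per `"sample"` (default; all
#' disease x bin tests of one sample), `"global"` (everything at once) or
#' `"per_disease"` (each sample x disease series).
#'
#' The zero-load bin is tested too and labelled bin_rank 0.
#'
#' @param partitions named list of `bin_partition` objects (one per sample).
#' @param disease_sets named list of disease gene sets (see
#'   [build_disease_sets()]); sets are intersected with each sample's
#'   population, a disjoint set simply yields k = 0, p = 1.
#' @param bh_family multiple-testing family (see above).
#' @return data.frame with one row per (sample, disease, bin):
#'   sample_id, disease_id, bin_rank, N, K, n, k, p_raw, p_adj,
#'   neg_log10_p_adj.
#' @export
enrich_matrix <- function(partitions, disease_sets,
                          bh_family = c("sample", "global", "per_disease")) {
  bh_family <- match.arg(bh_family)
  rows <- list()
  for (s in names(partitions)) {
    part <- partitions[[s]]
    pop <- part$population
    N <- length(pop)
    bins <- c(part$bins,
              list(list(bin_rank = 0L, genes = part$zero_bin)))
    for (d in names(disease_sets)) {
      dg <- intersect(disease_sets[[d]], pop)
      K <- length(dg)
      for (b in bins) {
        n <- length(b$genes)
        if (n == 0) next
        k <- length(intersect(dg, b$genes))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, disease_id = d, bin_rank = b$bin_rank,
          N = N, K = K, n = n, k = k,
          p_raw = hypergeom_upper_tail(N, K, n, k),
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, rows)
  cells$p_adj <- switch(bh_family,
    global = p.adjust(cells$p_raw, method = "BH"),
    sample = stats::ave(cells$p_raw, cells$sample_id,
                        FUN = function(p) p.adjust(p, method = "BH")),
    per_disease = stats::ave(cells$p_raw,
                             paste(cells$sample_id, cells$disease_id),
                             FUN = function(p) p.adjust(p, method = "BH")))
  cells$neg_log10_p_adj <- -log10(cells$p_adj)
  cells
}

#' Wide adjusted -log10 p matrix for one bin
#'
#' Extracts the (disease x sample) matrix of adjusted -log10 p-values for a
#' chosen bin rank (1 = top bin).
#'
#' @param cells long enrichment table from [enrich_matrix()].
#' @param bin_rank bin to extract (default 1, the top bin).
#' @return numeric matrix, diseases as rows, samples as columns.
#' @export
enrichment_wide <- function(cells, bin_rank = 1L) {
  sub <- cells[cells$bin_rank == bin_rank, , drop = FALSE]
  diseases <- sort(unique(sub$disease_id))
  samples <- sort(unique(sub$sample_id))
  mat <- matrix(NA_real_, length(diseases), length(samples),
                dimnames = list(diseases, samples))
  mat[cbind(match(sub$disease_id, diseases),
            match(sub$sample_id, samples))] <- sub$neg_log10_p_adj
  mat
}

#' Binarize an enrichment matrix
#'
#' Cells become 1 iff the adjusted -log10 p-value is >= `threshold`
#' (threshold inclusive: values strictly below it are 0). Rows and columns
#' containing only zeros are dropped and their ids reported.
#'
#' @param mat numeric matrix of adjusted -log10 p-values.
#' @param threshold significance threshold on the -log10 scale; the default
#'   `-log10(0.05)` is 1.301 at the conventional printing precision.
#' @return list with `matrix` (0/1), `dropped_rows`, `dropped_cols`.
#' @export
binarize <- function(mat, threshold = -log10(0.05)) {
  bin <- (mat >= threshold) * 1L
  bin[is.na(bin)] <- 0L
  keep_r <- rowSums(bin) > 0
  keep_c <- colSums(bin) > 0
  list(matrix = bin[keep_r, keep_c, drop = FALSE],
       dropped_rows = rownames(bin)[!keep_r],
       dropped_cols = colnames(bin)[!keep_c])
}
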