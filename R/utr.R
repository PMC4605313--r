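# 3' UTR length comparisons and miRNA binding-site counting.

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the background sample is stochastically SMALLER than the
#' test sample. The statistic is D+ = sup_x (F_background(x) - F_test(x));
#' under the alternative the test values are stochastically larger, pushing
#' F_test below F_background. The p-value uses the standard asymptotic
#' one-sided formula exp(-2 D+^2 m n / (m + n)), capped at 1 (and D+ <= 0
#' yields p = 1).
#'
#' @param background_values,test_values numeric vectors (non-empty).
#' @return list with `D_plus` and `p`.
#' @export
ks_one_sided <- function(background_values, test_values) {
  m <- length(background_values)
  n <- length(test_values)
  if (m == 0 || n == 0) stop("both samples must be non-empty")
  grid <- sort(unique(c(background_values, test_values)))
  Fb <- ecdf(background_values)(grid)
  Ft <- ecdf(test_values)(grid)
  D <- max(Fb - Ft)
  p <- if (D <= 0) 1 else min(1, exp(-2 * D^2 * m * n / (m + n)))
  list(D_plus = D, p = p)
}

#' Bonferroni per-test significance level
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests.
#' @return alpha / m.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Deduplicated miRNA binding-site counts per gene
#'
#' Sites sharing identical coordinates (gene_id, site_start, site_end) are
#' counted once regardless of how many miRNA family labels they carry;
#' overlapping but non-identical sites remain distinct.
#'
#' @param site_table data.frame with columns gene_id, site_start, site_end,
#'   mirna_family (positions are nt offsets within the 3' UTR).
#' @param utr3_lengths optional named vector of 3' UTR lengths; when given,
#'   any site extending beyond its gene's UTR is an error.
#' @return named integer vector: gene_id -> deduplicated site count.
#' @export
count_mirna_sites <- function(site_table, utr3_lengths = NULL) {
  if (!is.null(utr3_lengths)) {
    lim <- utr3_lengths[site_table$gene_id]
    if (any(is.na(lim)) || any(site_table$site_end > lim) ||
        any(site_table$site_start < 0)) {
      stop("miRNA site outside the annotated 3' UTR")
    }
  }
  uniq <- unique(site_table[, c("gene_id", "site_start", "site_end")])
  counts <- table(uniq$gene_id)
  setNames(as.integer(counts), names(counts))
}

#' Correlation between site count and distinct miRNA family count
#'
#' Spearman rank correlation, across genes with at least one site, between
#' the deduplicated site count and the number of distinct miRNA families
#' targeting the gene.
#'
#' @param site_table data.frame as in [count_mirna_sites()].
#' @return Spearman correlation coefficient in [-1, 1].
#' @export
site_family_correlation <- function(site_table) {
  counts <- count_mirna_sites(site_table)
  fams <- vapply(split(site_table$mirna_family, site_table$gene_id),
                 function(x) length(unique(x)), 0L)
  genes <- names(counts)
  suppressWarnings(cor(counts[genes], fams[genes], method = "spearman"))
}

#' Compare transcript-length distributions of high-load genes vs background
#'
#' Runs the one-sided KS test (background smaller than test) for each of
#' the annotated length columns and reports means and the Bonferroni
#' verdict at level `alpha / n_tests`.
#'
#' @param transcripts data.frame with columns gene_id, utr3_length,
#'   utr5_length, cds_length, spliced_length, unspliced_length.
#' @param hrl_genes character vector of high-regulatory-load gene ids.
#' @param background character vector of background gene ids; by default
#'   the high-load genes remain part of the background sample
#'   (subset-inclusive); set `exclude_test_from_background = TRUE` for the
#'   disjoint variant.
#' @param alpha family-wise level (default 0.05).
#' @param n_tests number of tests for the Bonferroni correction
#'   (default 139, one per sample in a full-scale screen).
#' @param exclude_test_from_background see above.
#' @return data.frame with one row per length feature: feature, mean_bg,
#'   mean_test, D_plus, p, significant.
#' @export
utr_length_test <- function(transcripts, hrl_genes,
                            background = transcripts$gene_id,
                            alpha = 0.05, n_tests = 139,
                            exclude_test_from_background = FALSE) {
  feats <- c("utr3_length", "utr5_length", "cds_length",
             "spliced_length", "unspliced_length")
  feats <- intersect(feats, names(transcripts))
  bg_ids <- intersect(background, transcripts$gene_id)
  if (exclude_test_from_background) bg_ids <- setdiff(bg_ids, hrl_genes)
  test_ids <- intersect(hrl_genes, transcripts$gene_id)
  rownames(transcripts) <- transcripts$gene_id
  level <- bonferroni_threshold(alpha, n_tests)
  rows <- lapply(feats, function(f) {
    bg <- transcripts[bg_ids, f]
    te <- transcripts[test_ids, f]
    ks <- ks_one_sided(bg, te)
    data.frame(feature = f, mean_bg = mean(bg), mean_test = mean(te),
               D_plus = ks$D_plus, p = ks$p,
               significant = ks$p <= level, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
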