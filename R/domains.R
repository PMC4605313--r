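# GREAT-style 'BasalPlusExtension' regulatory domains and peak-to-gene
# assignment.

#' Construct BasalPlusExtension regulatory domains
#'
#' Each gene receives a strand-aware basal domain around its TSS
#' (`basal_up` bp upstream, `basal_down` bp downstream) and an extended
#' domain reaching up to `max_ext` bp in both directions but stopping at the
#' basal domain of the nearest neighboring gene on the same chromosome
#' (upstream neighbor's basal end on the left, downstream neighbor's basal
#' start on the right). The gene's own basal domain is always unioned into
#' its extended domain, so `basal` is a subset of `domain` even when a
#' neighbor's basal region overlaps it. Everything is clipped to
#' `[0, chromosome length)`. Domains of adjacent genes may overlap.
#'
#' Neighbors are determined by TSS position; genes with identical TSS are
#' ordered lexicographically by `gene_id`.
#'
#' @param genes gene data.frame (gene_id, chrom, strand, tss).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param basal_up,basal_down basal extent upstream/downstream of the TSS
#'   in bp (GREAT defaults 5000 and 1000).
#' @param max_ext maximum extension from the TSS in bp (GREAT default 1e6).
#' @return data.frame with columns gene_id, chrom, strand, tss, basal_start,
#'   basal_end, domain_start, domain_end (row order = input order).
#' @export
create_regulatory_domains <- function(genes, chrom_sizes,
                                      basal_up = 5000, basal_down = 1000,
                                      max_ext = 1e6) {
  .check_gene_table(genes)
  .check_chrom_sizes(chrom_sizes)
  if (!all(genes$chrom %in% names(chrom_sizes))) {
    stop("unknown chromosome in gene table: ",
         paste(setdiff(genes$chrom, names(chrom_sizes)), collapse = ", "))
  }
  len <- unname(chrom_sizes[genes$chrom])
  if (any(genes$tss < 0 | genes$tss >= len)) {
    stop("TSS outside chromosome for gene(s): ",
         paste(genes$gene_id[genes$tss < 0 | genes$tss >= len], collapse = ", "))
  }

  tss <- genes$tss
  plus <- genes$strand == "+"
  basal_start <- ifelse(plus, tss - basal_up, tss - basal_down)
  basal_end <- ifelse(plus, tss + basal_down, tss + basal_up)
  basal_start <- pmax(basal_start, 0)
  basal_end <- pmin(basal_end, len)

  domain_start <- pmax(tss - max_ext, 0)
  domain_end <- pmin(tss + max_ext, len)

  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    ord <- idx[order(tss[idx], genes$gene_id[idx])]
    if (length(ord) > 1) {
      up <- c(NA, ord[-length(ord)])   # nearest upstream neighbor (by TSS)
      dn <- c(ord[-1], NA)             # nearest downstream neighbor
      has_up <- !is.na(up)
      has_dn <- !is.na(dn)
      domain_start[ord[has_up]] <- pmax(domain_start[ord[has_up]],
                                        basal_end[up[has_up]])
      domain_end[ord[has_dn]] <- pmin(domain_end[ord[has_dn]],
                                      basal_start[dn[has_dn]])
    }
  }

  # union with own basal so basal subset-of domain always holds
  domain_start <- pmin(domain_start, basal_start)
  domain_end <- pmax(domain_end, basal_end)

  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             strand = genes$strand, tss = tss,
             basal_start = basal_start, basal_end = basal_end,
             domain_start = domain_start, domain_end = domain_end,
             stringsAsFactors = FALSE)
}

#' Filter peaks on fold change and -log10 q-value
#'
#' Keeps peaks with `fold_change >= min_fold_change` AND
#' `neg_log10_q >= min_neg_log10_q` (thresholds inclusive); row order is
#' preserved. Used for consortium peak sets delivered with peak statistics.
#'
#' @param peaks peak data.frame carrying `fold_change` and `neg_log10_q`.
#' @param min_fold_change,min_neg_log10_q inclusive thresholds (default 3).
#' @return filtered peak data.frame.
#' @export
filter_peaks <- function(peaks, min_fold_change = 3, min_neg_log10_q = 3) {
  if (nrow(peaks) == 0) return(peaks)
  if (any(is.na(peaks$fold_change)) || any(is.na(peaks$neg_log10_q))) {
    stop("peaks lack fold_change / neg_log10_q values required for filtering")
  }
  keep <- peaks$fold_change >= min_fold_change &
    peaks$neg_log10_q >= min_neg_log10_q
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus peaks across replicates
#'
#' A peak from any replicate is retained iff the number of replicates
#' containing at least one peak overlapping it by >= 1 bp (its own replicate
#' counts) is at least `ceiling(2 n / 3)` for n replicates. Retained peaks
#' that overlap each other are merged by interval union.
#'
#' @param replicate_peaksets list of peak data.frames (>= 1).
#' @return peak data.frame of merged consensus intervals (stat columns NA).
#' @export
consensus_replicates <- function(replicate_peaksets) {
  n <- length(replicate_peaksets)
  if (n == 0) stop("empty replicate list")
  if (n == 1) return(replicate_peaksets[[1]])
  need <- ceiling(2 * n / 3)
  all_peaks <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- replicate_peaksets[[i]]
    if (nrow(p) == 0) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end, rep = i,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_peaks) || nrow(all_peaks) == 0) return(empty_peak_table())
  gr <- .as_granges(all_peaks)
  hits <- GenomicRanges::findOverlaps(gr, gr, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # per query peak: number of distinct replicates among its overlappers
  support <- vapply(split(all_peaks$rep[sh], qh), function(r) length(unique(r)), 0L)
  supported <- as.integer(names(support))[support >= need]
  if (length(supported) == 0) return(empty_peak_table())
  merged <- GenomicRanges::reduce(gr[supported])
  peak_table(as.character(GenomicRanges::seqnames(merged)),
             GenomicRanges::start(merged) - 1L,
             GenomicRanges::end(merged))
}

#' Identify open genes from H3K4me3 peaks
#'
#' A gene is "open" iff at least one H3K4me3 peak in at least one of the
#' supplied peak sets overlaps the window `TSS +/- window` by >= 1 bp
#' (overlap, not containment; evidence from a single file is sufficient).
#' The window covers positions `tss - window` .. `tss + window` inclusive.
#'
#' @param genes gene data.frame.
#' @param h3k4me3_peaksets list of peak data.frames (or a single one).
#' @param window half-width of the TSS window in bp (default 1000).
#' @return character vector of open gene ids.
#' @export
open_genes <- function(genes, h3k4me3_peaksets, window = 1000) {
  .check_gene_table(genes)
  if (is.data.frame(h3k4me3_peaksets)) h3k4me3_peaksets <- list(h3k4me3_peaksets)
  win <- data.frame(chrom = genes$chrom,
                    start = pmax(genes$tss - window, 0),
                    end = genes$tss + window + 1)
  win_gr <- .as_granges(win)
  open <- rep(FALSE, nrow(genes))
  for (p in h3k4me3_peaksets) {
    if (nrow(p) == 0) next
    hits <- GenomicRanges::findOverlaps(win_gr, .as_granges(p), minoverlap = 1L)
    open[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  genes$gene_id[open]
}

#' Assign peaks to regulatory domains by containment
#'
#' A peak is assigned to a gene iff it falls completely within the gene's
#' extended regulatory domain (`domain_start <= peak.start` and
#' `peak.end <= domain_end`). Because domains of neighboring genes overlap,
#' one peak may be assigned to several genes.
#'
#' @param domains domain data.frame from [create_regulatory_domains()].
#' @param peaks peak data.frame.
#' @return object of class `peak_assignment`: list with `assignments`
#'   (data.frame gene_id / peak_idx), `n_peaks`, `unassigned` (indices of
#'   peaks contained in no domain).
#' @export
assign_peaks <- function(domains, peaks) {
  if (nrow(peaks) == 0) {
    res <- list(assignments = data.frame(gene_id = character(),
                                         peak_idx = integer(),
                                         stringsAsFactors = FALSE),
                n_peaks = 0L, unassigned = integer())
    class(res) <- "peak_assignment"
    return(res)
  }
  dom_gr <- GenomicRanges::GRanges(
    seqnames = domains$chrom,
    ranges = IRanges::IRanges(start = domains$domain_start + 1L,
                              end = domains$domain_end))
  hits <- GenomicRanges::findOverlaps(.as_granges(peaks), dom_gr,
                                      type = "within")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  res <- list(
    assignments = data.frame(gene_id = domains$gene_id[sh],
                             peak_idx = qh, stringsAsFactors = FALSE),
    n_peaks = nrow(peaks),
    unassigned = setdiff(seq_len(nrow(peaks)), unique(qh)))
  class(res) <- "peak_assignment"
  res
}

#' @export
print.peak_assignment <- function(x, ...) {
  cat(sprintf("peak assignment: %d peaks, %d assignments, %d unassigned (%.1f%% assigned)\n",
              x$n_peaks, nrow(x$assignments), length(x$unassigned),
              if (x$n_peaks) 100 * (1 - length(x$unassigned) / x$n_peaks) else 0))
  invisible(x)
}
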