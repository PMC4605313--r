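# Internal helpers shared across modules.

# Canonical evidence labels from gene-disease association databases.
EVIDENCE_TYPES <- c(
  "altered expression", "biomarker", "genetic variation",
  "post-translational modification", "therapeutic"
)

#' Construct a peak table
#'
#' Peaks are plain data.frames with 0-based half-open coordinates, one row
#' per peak record. Records with identical coordinates are kept distinct
#' (they count separately towards enhancer load).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, `start < end`.
#' @param score,fold_change,neg_log10_q optional numeric vectors (NA allowed).
#' @return data.frame with columns chrom, start, end, score, fold_change,
#'   neg_log10_q.
#' @export
peak_table <- function(chrom, start, end, score = NA_real_,
                       fold_change = NA_real_, neg_log10_q = NA_real_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom) | !nzchar(chrom))) stop("peak chrom must be non-empty")
  if (any(is.na(start)) || any(is.na(end))) stop("peak coordinates must not be NA")
  if (any(start < 0)) stop("peak start must be >= 0")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("peak %d has start >= end (%s:%s-%s)", bad,
                 chrom[bad], start[bad], end[bad]))
  }
  data.frame(chrom = chrom, start = start, end = end,
             score = rep_len(as.numeric(score), length(chrom)),
             fold_change = rep_len(as.numeric(fold_change), length(chrom)),
             neg_log10_q = rep_len(as.numeric(neg_log10_q), length(chrom)),
             stringsAsFactors = FALSE)
}

# Empty peak table with the canonical columns.
empty_peak_table <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             score = numeric(), fold_change = numeric(),
             neg_log10_q = numeric(), stringsAsFactors = FALSE)
}

# GRanges view of a 0-based half-open interval table (chrom/start/end).
# IRanges is 1-based closed: [start+1, end].
.as_granges <- function(tab) {
  GenomicRanges::GRanges(
    seqnames = tab$chrom,
    ranges = IRanges::IRanges(start = tab$start + 1L, end = tab$end)
  )
}

.check_gene_table <- function(genes) {
  req <- c("gene_id", "chrom", "strand", "tss")
  if (!all(req %in% names(genes))) {
    stop("gene table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene_id: ", paste(head(dup, 5), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  invisible(genes)
}

.check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("chrom_sizes must be a named vector of chromosome lengths")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be > 0")
  invisible(chrom_sizes)
}
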