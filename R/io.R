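# Readers and writers for the plain-text formats the pipeline touches.
# All genomic files use BED semantics: 0-based half-open, tab-separated.

#' Read a BED-like peak file
#'
#' Supports three dialects: `bed3` (chrom/start/end), `bed6plus` (BED6 with
#' the score column parsed, extra columns ignored) and `peak_with_stats`
#' (narrowPeak-like; the columns holding the peak fold change and the
#' -log10 q-value are declared explicitly, defaulting to the narrowPeak
#' signalValue and qValue columns 7 and 9).
#'
#' @param path file path.
#' @param dialect one of "bed3", "bed6plus", "peak_with_stats".
#' @param fc_col,q_col 1-based column indices of fold change and -log10
#'   q-value for `peak_with_stats`.
#' @return peak data.frame (see [peak_table()]); row order follows the file.
#' @export
read_bed <- function(path, dialect = c("bed3", "bed6plus", "peak_with_stats"),
                     fc_col = 7L, q_col = 9L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_peak_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  need <- switch(dialect, bed3 = 3L, bed6plus = 3L,
                 peak_with_stats = max(3L, fc_col, q_col))
  if (any(ncols < need)) {
    bad <- which(ncols < need)[1]
    stop(sprintf("line %d of %s has %d fields (need >= %d)",
                 bad, path, ncols[bad], need))
  }
  get <- function(i) vapply(fields, `[`, "", i)
  chrom <- get(1L)
  start <- suppressWarnings(as.numeric(get(2L)))
  end <- suppressWarnings(as.numeric(get(3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("line %d of %s: non-integer coordinates", bad[1], path))
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("line %d of %s: start >= end", bad[1], path))
  }
  score <- NA_real_
  if (dialect != "bed3" && all(ncols >= 5L)) {
    score <- suppressWarnings(as.numeric(get(5L)))
  }
  fc <- q <- NA_real_
  if (dialect == "peak_with_stats") {
    fc <- suppressWarnings(as.numeric(get(fc_col)))
    q <- suppressWarnings(as.numeric(get(q_col)))
  }
  peak_table(chrom, start, end, score = score, fold_change = fc,
             neg_log10_q = q)
}

#' Write peaks as BED
#'
#' `bed3` writes chrom/start/end; `peak_with_stats` writes a narrowPeak-like
#' 9-column file that [read_bed()] reads back with its default stat columns.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @param dialect "bed3" or "peak_with_stats".
#' @export
write_bed <- function(peaks, path, dialect = c("bed3", "peak_with_stats")) {
  dialect <- match.arg(dialect)
  fmt_num <- function(x) ifelse(is.na(x), "0", format(x, trim = TRUE, scientific = FALSE))
  if (dialect == "bed3") {
    out <- data.frame(peaks$chrom, peaks$start, peaks$end)
  } else {
    out <- data.frame(peaks$chrom, peaks$start, peaks$end, ".", "0", ".",
                      fmt_num(peaks$fold_change), "-1", fmt_num(peaks$neg_log10_q))
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `strand`, `tss`.
#' The TSS is a 0-based point coordinate.
#'
#' @param path file path.
#' @return data.frame with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$gene_id <- as.character(tab$gene_id)
  tab$chrom <- as.character(tab$chrom)
  tab$strand <- as.character(tab$strand)
  tab$tss <- as.numeric(tab$tss)
  .check_gene_table(tab)
  tab[, c("gene_id", "chrom", "strand", "tss")]
}

#' Write a gene annotation table
#' @param genes gene data.frame.
#' @param path output path.
#' @export
write_gene_annotation <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "strand", "tss")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes
#'
#' Two tab-separated columns: chromosome name, length in bp (no header).
#'
#' @param path file path.
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  sizes <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  .check_chrom_sizes(sizes)
  sizes
}

#' Write chromosome sizes
#' @param chrom_sizes named numeric vector.
#' @param path output path.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  write.table(data.frame(names(chrom_sizes), unname(chrom_sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene-disease association table
#'
#' Tab-separated with header `gene_id`, `disease_id`, `score`,
#' `evidence_types`; the evidence field is a semicolon-separated list of
#' association-evidence labels (canonically one of: altered expression,
#' biomarker, genetic variation, post-translational modification,
#' therapeutic). Rows with the same (gene, disease) pair are collapsed to a
#' single record keeping the maximum score and the union of evidence types.
#' Unknown evidence labels raise a warning and are passed through.
#'
#' @param path file path.
#' @return data.frame with columns gene_id, disease_id, score,
#'   evidence_types (semicolon-joined, sorted).
#' @export
read_associations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "disease_id", "score", "evidence_types")
  if (!all(req %in% names(tab))) {
    stop("association table needs columns: ", paste(req, collapse = ", "))
  }
  tab$score <- as.numeric(tab$score)
  if (any(is.na(tab$score)) || any(tab$score < 0 | tab$score > 1)) {
    stop("association scores must lie in [0, 1]")
  }
  ev <- lapply(strsplit(as.character(tab$evidence_types), ";", fixed = TRUE),
               function(x) {
                 x <- tolower(trimws(x))
                 x[nzchar(x)]
               })
  if (any(lengths(ev) == 0)) stop("evidence_types must be non-empty")
  unknown <- setdiff(unique(unlist(ev)), EVIDENCE_TYPES)
  if (length(unknown)) {
    warning("unknown evidence label(s): ", paste(unknown, collapse = ", "))
  }
  key <- paste(tab$gene_id, tab$disease_id, sep = "\r")
  if (anyDuplicated(key)) {
    split_idx <- split(seq_along(key), key)
    idx <- vapply(split_idx, `[`, 0L, 1L)
    score <- vapply(split_idx, function(i) max(tab$score[i]), 0)
    ev2 <- lapply(split_idx, function(i) unique(unlist(ev[i])))
    tab <- tab[idx, , drop = FALSE]
    tab$score <- score
    ev <- ev2
  }
  data.frame(gene_id = as.character(tab$gene_id),
             disease_id = as.character(tab$disease_id),
             score = tab$score,
             evidence_types = vapply(ev, function(x) paste(sort(x), collapse = ";"), ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a gene-disease association table
#' @param associations data.frame as returned by [read_associations()].
#' @param path output path.
#' @export
write_associations <- function(associations, path) {
  write.table(associations[, c("gene_id", "disease_id", "score", "evidence_types")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway membership in GMT format
#'
#' One pathway per line: name, description, then member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors (gene sets), names = pathway ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  sets
}

#' Write pathway membership in GMT format
#' @param pathways named list of gene-id vectors.
#' @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(p) {
    paste(c(p, p, pathways[[p]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an undirected edge list
#'
#' Two whitespace-separated gene ids per line. Self-loops are dropped and
#' duplicate edges (in either orientation) collapsed.
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to` (from <= to lexicographically).
#' @export
read_edge_list <- function(path) {
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("from", "to"))
  normalize_edges(tab$from, tab$to)
}

#' Normalize an edge set
#'
#' Orients each undirected edge lexicographically, drops self-loops and
#' duplicates.
#' @param from,to character vectors of endpoint ids.
#' @return data.frame with columns `from`, `to`.
#' @export
normalize_edges <- function(from, to) {
  from <- as.character(from); to <- as.character(to)
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("edge endpoint ids must be non-empty")
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  dup <- duplicated(paste(a, b, sep = "\r"))
  data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
}

#' Write an edge list
#' @param edges data.frame with `from`, `to`.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  write.table(edges[, c("from", "to")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an enrichment matrix as TSV
#'
#' Diseases as rows, samples as columns, adjusted -log10 p-values as cells.
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @export
write_enrichment_matrix <- function(mat, path) {
  out <- data.frame(disease_id = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an enrichment matrix written by [write_enrichment_matrix()]
#' @param path file path.
#' @return numeric matrix (diseases x samples).
#' @export
read_enrichment_matrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  mat
}
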