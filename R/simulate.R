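# Synthetic-data generators. The generators emulate the statistical
# structure of multi-sample enhancer/promoter ChIP-Seq studies: per-gene
# enhancer counts are overdispersed (negative binomial via a shared
# gene-level gamma intensity, so samples of the same study are correlated),
# TF binding is generated conditionally on enhancer count (producing the
# positive TF-load/enhancer-load correlation), disease membership, pathway
# membership, network attachment and 3' UTR length are all optionally
# skewed towards the genes in the top load decile ("planted" mode).

#' Default simulation configuration
#'
#' Returns the study conditions used throughout: counts, distribution
#' parameters and planted effect sizes. Override any field by argument.
#'
#' @param ... named overrides of the defaults.
#' @return list of configuration values.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chroms = 3,
    chrom_length = 6e7,
    n_genes = 2000,
    n_samples = 4,
    n_tfs = 30,
    enhancer_mean = 6,          # negative-binomial mean of enhancer counts
    enhancer_dispersion = 1,    # NB size parameter (smaller = longer tail)
    sample_noise_shape = 8,     # gamma shape of per-sample count noise
    tf_load_slope = 0.5,        # expected TF events per enhancer peak
    open_fraction = 0.8,        # P(gene carries an H3K4me3 promoter peak)
    n_diseases = 50,
    genes_per_disease = c(15, 100),
    enrichment_odds = 4,        # odds multiplier for top-decile genes (1 = null)
    score_frac_supported = 0.85, # fraction of association scores >= 0.08
    evidence_weights = c("genetic variation" = 0.35, "biomarker" = 0.30,
                         "altered expression" = 0.20, "therapeutic" = 0.10,
                         "post-translational modification" = 0.05),
    n_pathways = 40,
    pathway_size = c(10, 80),
    pathway_load_bias = 1.5,    # membership odds multiplier for top decile
    ppi_edges = 6000,
    ppi_hub_bias = 5,           # base attachment weight of top-decile genes
    utr3_meanlog = log(1213) - 0.5, # lognormal(meanlog, sdlog=1) has mean 1213 nt
    utr3_sdlog = 1,
    utr3_shift = log(1.39),     # log-mean shift for top-decile genes (+39% mean)
    mirna_rate_per_kb = 5,      # Poisson rate of sites along the 3' UTR
    mirna_multi_label_frac = 0.1, # sites additionally listed under a 2nd family
    n_mirna_families = 80,
    peak_width_enhancer = 500,
    peak_width_tf = 300,
    peak_width_promoter = 1000
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$open_fraction > 0, cfg$open_fraction <= 1,
            cfg$enrichment_odds >= 1, cfg$n_genes > 0, cfg$n_samples > 0)
  cfg
}

#' Generate a synthetic genome and gene annotation
#'
#' Places `n_genes` genes uniformly over `n_chroms` chromosomes with a
#' guaranteed minimum TSS spacing of 2 kb and random strands.
#'
#' @param config configuration from [sim_config()].
#' @param seed integer seed.
#' @return list with `chrom_sizes` (named vector) and `genes` (data.frame).
#' @export
generate_genome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  sizes <- setNames(rep(config$chrom_length, config$n_chroms),
                    paste0("chr", seq_len(config$n_chroms)))
  per <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  min_gap <- 2000
  rows <- list()
  gid <- 0L
  for (i in seq_len(config$n_chroms)) {
    k <- per[i]
    if (k == 0) next
    L <- sizes[i]
    slack <- L - 1 - (k - 1) * min_gap
    if (slack <= 0) stop("genes cannot fit on chromosome with 2 kb spacing")
    tss <- floor(sort(runif(k, 0, slack)) + (seq_len(k) - 1) * min_gap)
    rows[[i]] <- data.frame(
      gene_id = sprintf("g%05d", gid + seq_len(k)),
      chrom = names(sizes)[i],
      strand = sample(c("+", "-"), k, replace = TRUE),
      tss = tss, stringsAsFactors = FALSE)
    gid <- gid + k
  }
  list(chrom_sizes = sizes, genes = do.call(rbind, rows))
}

#' Generate per-sample peak sets
#'
#' For each sample: open genes (probability `open_fraction`) receive one
#' H3K4me3 peak overlapping the TSS; every gene receives a number of
#' H3K27ac enhancer peaks drawn as Poisson around a shared gene-level gamma
#' intensity (negative-binomial marginal with mean `enhancer_mean` and size
#' `enhancer_dispersion`; the shared intensity makes samples of one study
#' correlated), placed uniformly inside the gene's regulatory domain; TF
#' binding events are Poisson with expectation `tf_load_slope` times the
#' enhancer count, each event labelled with one of `n_tfs` TFs. Peak
#' statistics (fold change, -log10 q) are drawn above the conventional
#' filtering threshold.
#'
#' @param genes gene data.frame.
#' @param domains regulatory domains for the genes.
#' @param config configuration.
#' @param seed integer seed.
#' @return named list of samples; each a list with `sample_id`, `cell_type`,
#'   `h3k4me3`, `h3k27ac`, `tf_peaks` (named list per TF), and
#'   `enhancer_count` (the generated per-gene counts).
#' @export
generate_peaks <- function(genes, domains, config = sim_config(), seed = 1L) {
  set.seed(seed)
  ng <- nrow(genes)
  # shared gene-level regulatory intensity (gamma -> NB marginal)
  u <- if (config$enhancer_mean <= 0) rep(0, ng) else
    rgamma(ng, shape = config$enhancer_dispersion,
           scale = config$enhancer_mean / config$enhancer_dispersion)
  dom_w <- domains$domain_end - domains$domain_start
  cell_types <- c("cellA", "cellA",
                  paste0("cell", LETTERS[2 + seq_len(max(0, config$n_samples - 2))]))
  samples <- list()
  for (s in seq_len(config$n_samples)) {
    sid <- sprintf("sample%02d", s)
    open <- runif(ng) < config$open_fraction
    v <- rgamma(ng, shape = config$sample_noise_shape,
                rate = config$sample_noise_shape)
    cnt <- rpois(ng, u * v)

    # promoter peaks for open genes
    half <- config$peak_width_promoter / 2
    k4 <- peak_table(genes$chrom[open],
                     pmax(genes$tss[open] - half, 0),
                     genes$tss[open] + half,
                     fold_change = 3 + rexp(sum(open), 0.5),
                     neg_log10_q = 3 + rexp(sum(open), 0.2))

    place <- function(gene_idx, width) {
      w <- pmin(width, dom_w[gene_idx])
      lo <- domains$domain_start[gene_idx]
      hi <- domains$domain_end[gene_idx] - w
      st <- floor(runif(length(gene_idx), lo, hi + 1))
      peak_table(domains$chrom[gene_idx], st, st + w,
                 fold_change = 3 + rexp(length(gene_idx), 0.5),
                 neg_log10_q = 3 + rexp(length(gene_idx), 0.2))
    }
    too_small <- dom_w < config$peak_width_enhancer / 2
    if (any(too_small & cnt > 0)) {
      warning("regulatory domain too small for enhancer peaks; counts truncated")
      cnt[too_small] <- 0L
    }
    enh_idx <- rep(seq_len(ng), cnt)
    k27 <- if (length(enh_idx)) place(enh_idx, config$peak_width_enhancer)
           else empty_peak_table()

    ev <- rpois(ng, config$tf_load_slope * cnt)
    ev_idx <- rep(seq_len(ng), ev)
    tf_peaks <- list()
    if (length(ev_idx)) {
      tf_of <- sample(config$n_tfs, length(ev_idx), replace = TRUE)
      all_tf <- place(ev_idx, config$peak_width_tf)
      for (tf in sort(unique(tf_of))) {
        tf_peaks[[sprintf("TF%02d", tf)]] <-
          all_tf[tf_of == tf, , drop = FALSE]
      }
    }
    samples[[sid]] <- list(sample_id = sid, cell_type = cell_types[s],
                           h3k4me3 = k4, h3k27ac = k27, tf_peaks = tf_peaks,
                           enhancer_count = setNames(cnt, genes$gene_id))
  }
  samples
}

#' Generate a synthetic gene-disease association table
#'
#' Each disease samples its genes with probability proportional to 1 for
#' genes outside the planted set and `enrichment_odds` for planted
#' (top-decile-load) genes; with odds 1 the table carries no systematic
#' association with load (null mode). Scores are drawn so that a fraction
#' `score_frac_supported` exceeds 0.08; evidence types follow the
#' configured mixture, occasionally two per record.
#'
#' @param genes gene data.frame.
#' @param planted_set character vector of top-decile gene ids.
#' @param config configuration.
#' @param seed integer seed.
#' @return association data.frame (gene_id, disease_id, score,
#'   evidence_types).
#' @export
generate_disease_db <- function(genes, planted_set, config = sim_config(),
                                seed = 1L) {
  set.seed(seed)
  rng <- config$genes_per_disease
  if (max(rng) > nrow(genes)) stop("genes_per_disease exceeds n_genes")
  w <- ifelse(genes$gene_id %in% planted_set, config$enrichment_odds, 1)
  ev_names <- names(config$evidence_weights)
  rows <- list()
  for (d in seq_len(config$n_diseases)) {
    m <- sample(seq(rng[1], rng[2]), 1)
    gs <- sample(genes$gene_id, m, prob = w)
    supported <- runif(m) < config$score_frac_supported
    score <- ifelse(supported, runif(m, 0.08, 1), runif(m, 0.005, 0.079))
    n_ev <- 1 + (runif(m) < 0.25)
    ev <- vapply(n_ev, function(k) {
      paste(sort(sample(ev_names, k, prob = config$evidence_weights)),
            collapse = ";")
    }, "")
    rows[[d]] <- data.frame(gene_id = gs,
                            disease_id = sprintf("D%03d", d),
                            score = score, evidence_types = ev,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate pathway membership and a PPI edge list
#'
#' Pathway membership probability is multiplied by `pathway_load_bias` for
#' planted genes. The PPI is grown by degree-preferential attachment with
#' planted genes given a higher base attachment weight (`ppi_hub_bias`), so
#' hubs exist and tend to be high-load genes; the edge set is undirected
#' with no self-loops or duplicates and exactly `ppi_edges` edges.
#'
#' @param genes gene data.frame.
#' @param planted_set character vector of planted gene ids.
#' @param config configuration.
#' @param seed integer seed.
#' @return list with `pathways` (named list of gene sets) and `ppi_edges`
#'   (data.frame from/to).
#' @export
generate_pathways_network <- function(genes, planted_set,
                                      config = sim_config(), seed = 1L) {
  set.seed(seed)
  ids <- genes$gene_id
  planted <- ids %in% planted_set
  pw_w <- ifelse(planted, config$pathway_load_bias, 1)
  pathways <- list()
  for (p in seq_len(config$n_pathways)) {
    s <- sample(seq(config$pathway_size[1], config$pathway_size[2]), 1)
    pathways[[sprintf("P%03d", p)]] <- sample(ids, s, prob = pw_w)
  }

  n <- length(ids)
  E <- config$ppi_edges
  if (E > n * (n - 1) / 2) stop("ppi_edges exceeds the number of gene pairs")
  base <- ifelse(planted, config$ppi_hub_bias, 1)
  deg <- numeric(n)
  from <- to <- integer(E)
  seen <- new.env(hash = TRUE, size = 2 * E)
  e <- 0L
  while (e < E) {
    pick <- sample.int(n, 2, prob = deg + base)
    key <- paste(min(pick), max(pick))
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    e <- e + 1L
    from[e] <- pick[1]; to[e] <- pick[2]
    deg[pick] <- deg[pick] + 1
  }
  list(pathways = pathways,
       ppi_edges = normalize_edges(ids[from], ids[to]))
}

#' Generate transcript annotation and miRNA site tables
#'
#' 3' UTR lengths are lognormal with the log-mean shifted by `utr3_shift`
#' for planted genes (the default shift raises the mean by 39%). miRNA
#' sites are placed as a Poisson process along each 3' UTR (7-nt sites,
#' `mirna_rate_per_kb` per kb) with random family labels; a fraction of
#' sites is listed again under a second family at identical coordinates to
#' exercise the downstream deduplication rule.
#'
#' @param genes gene data.frame.
#' @param planted_set character vector of planted gene ids.
#' @param config configuration.
#' @param seed integer seed.
#' @return list with `transcripts` (data.frame) and `mirna_sites`
#'   (data.frame gene_id, site_start, site_end, mirna_family).
#' @export
generate_utr_annotation <- function(genes, planted_set,
                                    config = sim_config(), seed = 1L) {
  set.seed(seed)
  ng <- nrow(genes)
  planted <- genes$gene_id %in% planted_set
  utr3 <- pmax(20, round(rlnorm(ng, config$utr3_meanlog +
                                  config$utr3_shift * planted,
                                config$utr3_sdlog)))
  utr5 <- pmax(10, round(rlnorm(ng, log(150), 0.6)))
  cds <- pmax(100, round(rlnorm(ng, log(1200), 0.6)))
  spliced <- utr5 + cds + utr3
  unspliced <- round(spliced * (1 + rgamma(ng, shape = 2, rate = 1)))
  transcripts <- data.frame(gene_id = genes$gene_id, utr3_length = utr3,
                            utr5_length = utr5, cds_length = cds,
                            spliced_length = spliced,
                            unspliced_length = unspliced,
                            stringsAsFactors = FALSE)
  site_w <- 7
  n_sites <- rpois(ng, config$mirna_rate_per_kb * utr3 / 1000)
  n_sites[utr3 < site_w] <- 0L
  idx <- rep(seq_len(ng), n_sites)
  sites <- if (length(idx)) {
    st <- floor(runif(length(idx), 0, utr3[idx] - site_w + 1))
    data.frame(gene_id = genes$gene_id[idx], site_start = st,
               site_end = st + site_w,
               mirna_family = sprintf("miR-%03d",
                                      sample(config$n_mirna_families,
                                             length(idx), replace = TRUE)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), site_start = numeric(),
               site_end = numeric(), mirna_family = character(),
               stringsAsFactors = FALSE)
  }
  if (nrow(sites) && config$mirna_multi_label_frac > 0) {
    dupe <- which(runif(nrow(sites)) < config$mirna_multi_label_frac)
    if (length(dupe)) {
      extra <- sites[dupe, , drop = FALSE]
      extra$mirna_family <- sprintf("miR-%03d",
                                    sample(config$n_mirna_families,
                                           length(dupe), replace = TRUE))
      sites <- rbind(sites, extra)
      rownames(sites) <- NULL
    }
  }
  list(transcripts = transcripts, mirna_sites = sites)
}

#' Simulate a complete study
#'
#' Orchestrates all generators: genome, regulatory domains, per-sample
#' peaks, then (using the measured enhancer load of sample 1 among its open
#' genes to define the planted top decile) the disease association table,
#' pathways, PPI network, transcript annotation, miRNA sites and a
#' per-sample expression table correlated with load. The returned `truth`
#' element records the planted high-load gene set and, in planted mode, the
#' disease ids carrying the planted excess.
#'
#' @param config configuration from [sim_config()].
#' @param seed integer seed controlling every generator.
#' @return list with chrom_sizes, genes, domains, samples, associations,
#'   pathways, ppi_edges, transcripts, mirna_sites, expression (matrix),
#'   truth, config, seed.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  genome <- generate_genome(config, seed)
  domains <- create_regulatory_domains(genome$genes, genome$chrom_sizes)
  samples <- generate_peaks(genome$genes, domains, config, seed + 1000L)

  # measure the enhancer load of sample 1 with the pipeline's own assignment
  s1 <- samples[[1]]
  open1 <- open_genes(genome$genes, list(s1$h3k4me3))
  lt1 <- enhancer_load(assign_peaks(domains, s1$h3k27ac), genome$genes, open1)
  open_tab <- lt1[lt1$open, , drop = FALSE]
  ord <- order(-open_tab$load, open_tab$gene_id)
  planted <- open_tab$gene_id[ord][seq_len(ceiling(0.1 * nrow(open_tab)))]

  assoc <- generate_disease_db(genome$genes, planted, config, seed + 2000L)
  pn <- generate_pathways_network(genome$genes, planted, config, seed + 3000L)
  utr <- generate_utr_annotation(genome$genes, planted, config, seed + 4000L)

  set.seed(seed + 5000L)
  expr <- vapply(samples, function(s) {
    load_s <- s$enhancer_count
    rlnorm(length(load_s), meanlog = 0.5 * log1p(load_s), sdlog = 1)
  }, numeric(nrow(genome$genes)))
  rownames(expr) <- genome$genes$gene_id

  list(chrom_sizes = genome$chrom_sizes, genes = genome$genes,
       domains = domains, samples = samples, associations = assoc,
       pathways = pn$pathways, ppi_edges = pn$ppi_edges,
       transcripts = utr$transcripts, mirna_sites = utr$mirna_sites,
       expression = expr,
       truth = list(planted_hrl = planted,
                    planted_diseases = if (config$enrichment_odds > 1)
                      sprintf("D%03d", seq_len(config$n_diseases))
                    else character(0)),
       config = config, seed = seed)
}

#' Write a simulated study to a directory
#'
#' Emits chrom.sizes, genes.tsv, per-sample peak BED files, the
#' association table, pathways.gmt, ppi.tsv, transcripts.tsv,
#' mirna_sites.tsv, expression.tsv and the ground-truth ledger truth.json.
#'
#' @param sim study from [simulate_study()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_chrom_sizes(sim$chrom_sizes, fp("chrom.sizes"))
  write_gene_annotation(sim$genes, fp("genes.tsv"))
  for (s in sim$samples) {
    write_bed(s$h3k4me3, fp(sprintf("%s_H3K4me3.narrowPeak", s$sample_id)),
              dialect = "peak_with_stats")
    write_bed(s$h3k27ac, fp(sprintf("%s_H3K27ac.narrowPeak", s$sample_id)),
              dialect = "peak_with_stats")
    for (tf in names(s$tf_peaks)) {
      write_bed(s$tf_peaks[[tf]],
                fp(sprintf("%s_%s.narrowPeak", s$sample_id, tf)),
                dialect = "peak_with_stats")
    }
  }
  write_associations(sim$associations, fp("associations.tsv"))
  write_gmt(sim$pathways, fp("pathways.gmt"))
  write_edge_list(sim$ppi_edges, fp("ppi.tsv"))
  write.table(sim$transcripts, fp("transcripts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$mirna_sites, fp("mirna_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = rownames(sim$expression), sim$expression),
              fp("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(sim$truth, fp("truth.json"), auto_unbox = FALSE)
  invisible(dir)
}
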