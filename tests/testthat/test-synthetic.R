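test_that("genome generation is deterministic with spaced TSS placement", {
  cfg <- sim_config(n_genes = 60, n_chroms = 2, chrom_length = 1e6)
  g1 <- generate_genome(cfg, seed = 1)
  g2 <- generate_genome(cfg, seed = 1)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_genome(cfg, seed = 2)))
  expect_equal(nrow(g1$genes), 60)
  expect_true(all(g1$genes$tss >= 0 & g1$genes$tss < 1e6))
  for (seed in 1:25) {
    g <- generate_genome(cfg, seed = seed)
    gaps <- unlist(tapply(g$genes$tss, g$genes$chrom,
                          function(x) diff(sort(x))))
    expect_gte(min(gaps), 2000)
  }
  tiny <- sim_config(n_genes = 1000, n_chroms = 1, chrom_length = 1e6)
  expect_error(generate_genome(tiny, seed = 1), "cannot fit")
})

test_that("peak generation respects openness and degenerate settings", {
  cfg <- sim_config(n_genes = 150, n_samples = 1, open_fraction = 1)
  genome <- generate_genome(cfg, seed = 3)
  dom <- create_regulatory_domains(genome$genes, genome$chrom_sizes)
  smp <- generate_peaks(genome$genes, dom, cfg, seed = 3)[[1]]
  expect_setequal(open_genes(genome$genes, list(smp$h3k4me3)),
                  genome$genes$gene_id)  # every gene open downstream

  cfg0 <- sim_config(n_genes = 100, n_samples = 1, enhancer_mean = 0)
  genome0 <- generate_genome(cfg0, seed = 4)
  dom0 <- create_regulatory_domains(genome0$genes, genome0$chrom_sizes)
  smp0 <- generate_peaks(genome0$genes, dom0, cfg0, seed = 4)[[1]]
  expect_equal(nrow(smp0$h3k27ac), 0)
  open0 <- open_genes(genome0$genes, list(smp0$h3k4me3))
  lt0 <- enhancer_load(assign_peaks(dom0, smp0$h3k27ac), genome0$genes, open0)
  part0 <- bin_by_load(lt0)
  expect_equal(length(part0$bins), 0)  # all genes land in the zero bin
  expect_setequal(part0$zero_bin, open0)

  # determinism
  smp_a <- generate_peaks(genome$genes, dom, cfg, seed = 9)
  smp_b <- generate_peaks(genome$genes, dom, cfg, seed = 9)
  expect_identical(smp_a, smp_b)
})

test_that("TF load correlates positively with enhancer load as generated", {
  cfg <- sim_config(n_samples = 1, tf_load_slope = 0.5)
  sim <- simulate_study(cfg, seed = 5)
  s <- sim$samples[[1]]
  open <- open_genes(sim$genes, list(s$h3k4me3))
  lt <- enhancer_load(assign_peaks(sim$domains, s$h3k27ac), sim$genes, open)
  tfa <- lapply(s$tf_peaks, function(p) assign_peaks(sim$domains, p))
  tl <- tf_load(tfa, sim$genes, open)
  ok <- lt$open
  rho <- cor(tl$load[ok], lt$load[ok], method = "spearman")
  expect_gt(rho, 0.4)
  expect_true(all(tl$load <= length(s$tf_peaks)))
})

test_that("planted disease tables oversample the top decile; null tables do not", {
  cfg <- sim_config(n_genes = 500, n_diseases = 20,
                    genes_per_disease = c(20, 20), enrichment_odds = 4)
  genome <- generate_genome(cfg, seed = 6)
  planted <- genome$genes$gene_id[1:50]
  assoc <- generate_disease_db(genome$genes, planted, cfg, seed = 6)
  frac_planted <- mean(assoc$gene_id %in% planted)
  # expected fraction 4*50 / (4*50 + 450) ~ 0.308 vs background 0.1
  expect_gt(frac_planted, 0.2)
  q <- 4 * 50 / (4 * 50 + 450)
  se <- sqrt(q * (1 - q) / nrow(assoc))
  expect_lt(abs(frac_planted - q), 4 * se)

  null_cfg <- sim_config(n_genes = 500, n_diseases = 20,
                         genes_per_disease = c(20, 20), enrichment_odds = 1)
  null_assoc <- generate_disease_db(genome$genes, planted, null_cfg, seed = 7)
  f0 <- mean(null_assoc$gene_id %in% planted)
  expect_lt(abs(f0 - 0.1), 4 * sqrt(0.1 * 0.9 / nrow(null_assoc)))

  expect_identical(assoc, generate_disease_db(genome$genes, planted, cfg,
                                              seed = 6))
  bad <- sim_config(n_genes = 500, genes_per_disease = c(600, 700))
  expect_error(generate_disease_db(genome$genes, planted, bad, seed = 1),
               "exceeds n_genes")
})

test_that("generated pathways and PPI meet their structural contracts", {
  cfg <- sim_config(n_genes = 300, n_pathways = 15, ppi_edges = 800)
  genome <- generate_genome(cfg, seed = 8)
  planted <- genome$genes$gene_id[1:30]
  pn <- generate_pathways_network(genome$genes, planted, cfg, seed = 8)
  expect_equal(length(pn$pathways), 15)
  expect_equal(nrow(pn$ppi_edges), 800)        # exact configured edge count
  expect_true(all(pn$ppi_edges$from != pn$ppi_edges$to))
  expect_equal(anyDuplicated(paste(pn$ppi_edges$from, pn$ppi_edges$to)), 0)
  sizes <- lengths(pn$pathways)
  expect_true(all(sizes >= 10 & sizes <= 80))

  # null pathway bias: planted and background membership rates comparable
  null_cfg <- sim_config(n_genes = 300, n_pathways = 40,
                         pathway_size = c(30, 60), pathway_load_bias = 1)
  pn0 <- generate_pathways_network(genome$genes, planted, null_cfg, seed = 9)
  counts <- table(factor(unlist(pn0$pathways), levels = genome$genes$gene_id))
  m_planted <- mean(counts[planted])
  m_rest <- mean(counts[setdiff(genome$genes$gene_id, planted)])
  expect_lt(abs(m_planted - m_rest), 0.5)
})

test_that("UTR generator shifts planted genes and site counts track UTR length", {
  cfg <- sim_config(n_genes = 2000)
  genome <- generate_genome(cfg, seed = 10)
  planted <- genome$genes$gene_id[1:200]
  utr <- generate_utr_annotation(genome$genes, planted, cfg, seed = 10)
  tr <- utr$transcripts
  expect_true(all(tr$spliced_length <= tr$unspliced_length))
  # medians estimate exp(meanlog) tightly despite the lognormal tail
  ratio <- stats::median(tr$utr3_length[tr$gene_id %in% planted]) /
    stats::median(tr$utr3_length[!tr$gene_id %in% planted])
  expect_gt(ratio, 1.15)  # log-mean shift of log(1.39) in expectation

  # Poisson site placement: per-gene counts scale with UTR length
  counts <- count_mirna_sites(utr$mirna_sites)
  len <- setNames(tr$utr3_length, tr$gene_id)
  long <- len >= stats::median(len)
  expect_gt(mean(counts[names(len)[long]], na.rm = TRUE),
            mean(counts[names(len)[!long]], na.rm = TRUE))
  rate_hat <- sum(counts) / sum(tr$utr3_length / 1000)
  expect_lt(abs(rate_hat - cfg$mirna_rate_per_kb) / cfg$mirna_rate_per_kb, 0.25)

  none <- sim_config(n_genes = 200, mirna_rate_per_kb = 0)
  utr0 <- generate_utr_annotation(genome$genes[1:200, ], planted, none,
                                  seed = 2)
  expect_equal(nrow(utr0$mirna_sites), 0)
})

test_that("simulate_study is reproducible and writes a loadable directory", {
  cfg <- sim_config(n_genes = 200, n_samples = 2, n_diseases = 5,
                    genes_per_disease = c(10, 15), ppi_edges = 300)
  s1 <- simulate_study(cfg, seed = 11)
  s2 <- simulate_study(cfg, seed = 11)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$associations, s2$associations)

  dir <- withr::local_tempdir()
  write_simulation(s1, dir)
  expect_true(file.exists(file.path(dir, "truth.json")))
  genes <- read_gene_annotation(file.path(dir, "genes.tsv"))
  expect_equal(genes, s1$genes, ignore_attr = TRUE)
  k27 <- read_bed(file.path(dir, "sample01_H3K27ac.narrowPeak"),
                  "peak_with_stats")
  expect_equal(k27$start, s1$samples[[1]]$h3k27ac$start)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$planted_hrl, s1$truth$planted_hrl)
})
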