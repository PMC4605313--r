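test_that("a lone gene's domain spans basal plus extension clipped to the chromosome", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 500000, stringsAsFactors = FALSE)
  d <- create_regulatory_domains(genes, c(chr1 = 1e6))
  expect_equal(d$basal_start, 495000)
  expect_equal(d$basal_end, 501000)
  expect_equal(d$domain_start, 0)
  expect_equal(d$domain_end, 1e6)
})

test_that("neighboring basal domains bound the extension (3-gene worked case)", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      strand = c("+", "+", "-"),
                      tss = c(100000, 300000, 310000), stringsAsFactors = FALSE)
  d <- create_regulatory_domains(genes, c(chr1 = 1e6))
  expect_equal(d$basal_start, c(95000, 295000, 309000))
  expect_equal(d$basal_end, c(101000, 301000, 315000))
  expect_equal(d$domain_start, c(0, 101000, 301000))
  expect_equal(d$domain_end, c(295000, 309000, 1e6))
})

test_that("minus-strand basal orientation and clipping at both chromosome ends", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                      tss = 3000, stringsAsFactors = FALSE)
  d <- create_regulatory_domains(genes, c(chr1 = 10000))
  expect_equal(d$basal_start, 2000)
  expect_equal(d$basal_end, 8000)
  expect_equal(d$domain_start, 0)
  expect_equal(d$domain_end, 10000)
})

test_that("domain construction rejects TSS outside the chromosome", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
                      tss = 2e6, stringsAsFactors = FALSE)
  expect_error(create_regulatory_domains(genes, c(chr1 = 1e6)), "TSS outside")
  genes$chrom <- "chrX"
  expect_error(create_regulatory_domains(genes, c(chr1 = 1e6)),
               "unknown chromosome")
})

test_that("basal subset-of domain subset-of chromosome holds on random genomes", {
  for (seed in 1:20) {
    fx <- random_fixture(sample(5:40, 1), 0, seed)
    d <- create_regulatory_domains(fx$genes, fx$sizes)
    expect_true(all(d$domain_start <= d$basal_start))
    expect_true(all(d$basal_end <= d$domain_end))
    expect_true(all(d$domain_start >= 0))
    expect_true(all(d$domain_end <= fx$sizes[d$chrom]))
    # independent check of the neighbor rule: recompute with a direct loop
    for (ch in unique(d$chrom)) {
      dd <- d[d$chrom == ch, ]
      dd <- dd[order(dd$tss, dd$gene_id), ]
      n <- nrow(dd)
      for (i in seq_len(n)) {
        exp_start <- max(dd$tss[i] - 1e6, 0,
                         if (i > 1) dd$basal_end[i - 1] else 0)
        exp_end <- min(dd$tss[i] + 1e6, fx$sizes[ch],
                       if (i < n) dd$basal_start[i + 1] else Inf)
        expect_equal(dd$domain_start[i], min(exp_start, dd$basal_start[i]))
        expect_equal(dd$domain_end[i], max(exp_end, dd$basal_end[i]))
      }
    }
  }
})

test_that("peak filtering keeps the inclusive threshold and preserves order", {
  p <- peak_table(rep("chr1", 4), c(0, 100, 200, 300), c(50, 150, 250, 350),
                  fold_change = c(3.0, 10, 2.9, 5),
                  neg_log10_q = c(3.0, 2.9, 10, 5))
  f <- filter_peaks(p)
  expect_equal(f$start, c(0, 300))  # fc>=3 AND q>=3, boundary kept
  expect_error(filter_peaks(peak_table("chr1", 0, 10)), "lack fold_change")

  set.seed(1)
  st <- sample(0:1e5, 1000)
  p <- peak_table("chr1", st, st + 100, fold_change = runif(1000, 0, 6),
                  neg_log10_q = runif(1000, 0, 6))
  keep <- p$fold_change >= 3 & p$neg_log10_q >= 3  # predicate oracle
  expect_equal(filter_peaks(p)$start, p$start[keep])
})

test_that("replicate consensus keeps peaks supported by two thirds of replicates", {
  r1 <- peak_table("chr1", c(100, 5000), c(200, 5100))
  r2 <- peak_table("chr1", 150, 260)
  r3 <- peak_table("chr1", 9000, 9100)
  cons <- consensus_replicates(list(r1, r2, r3))
  # the 100-260 cluster is present in 2 of 3 replicates -> kept and merged;
  # singleton peaks at 5000 and 9000 are dropped
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 260)

  # n=2 identical replicates: ceiling(4/3)=2, everything survives, merged
  both <- peak_table("chr1", c(10, 100), c(20, 120))
  cons2 <- consensus_replicates(list(both, both))
  expect_equal(cons2$start, c(10, 100))
  expect_equal(cons2$end, c(20, 120))

  expect_error(consensus_replicates(list()), "empty")
})

test_that("open-gene calling uses >=1 bp overlap with TSS +/- 1000", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
                      tss = c(10000, 50000), stringsAsFactors = FALSE)
  # 1 bp overlap at the right window edge -> open
  p_edge <- peak_table("chr1", 10000 + 999, 10000 + 1500)
  expect_equal(open_genes(genes, p_edge), "g1")
  # just beyond the window -> closed
  p_out <- peak_table("chr1", 10000 + 2001, 10000 + 3000)
  expect_equal(open_genes(genes, p_out), character(0))
  # evidence from any one of several files suffices
  expect_equal(open_genes(genes, list(p_out, p_edge)), "g1")
  expect_equal(open_genes(genes, empty_peak_table()), character(0))
})

test_that("open-gene calling matches the brute-force overlap scan", {
  for (seed in 1:10) {
    fx <- random_fixture(30, 150, seed + 100)
    expect_setequal(open_genes(fx$genes, fx$peaks),
                    brute_open(fx$genes, fx$peaks))
  }
})

test_that("peak assignment is containment, not overlap, and allows multi-gene hits", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      strand = c("+", "+", "-"),
                      tss = c(100000, 300000, 310000), stringsAsFactors = FALSE)
  d <- create_regulatory_domains(genes, c(chr1 = 1e6))
  peaks <- peak_table("chr1", c(150000, 294500), c(150500, 295500))
  asg <- assign_peaks(d, peaks)
  hit1 <- asg$assignments$gene_id[asg$assignments$peak_idx == 1]
  expect_setequal(hit1, c("g1", "g2"))  # overlapping domains: both genes
  hit2 <- asg$assignments$gene_id[asg$assignments$peak_idx == 2]
  expect_false("g1" %in% hit2)  # straddles g1's boundary -> not contained
  expect_setequal(hit2, "g2")
})

test_that("interval assignment equals the brute-force containment scan", {
  for (seed in 1:10) {
    fx <- random_fixture(40, 300, seed + 200)
    d <- create_regulatory_domains(fx$genes, fx$sizes)
    got <- assign_peaks(d, fx$peaks)$assignments
    want <- brute_assign(d, fx$peaks)
    expect_setequal(paste(got$gene_id, got$peak_idx),
                    paste(want$gene_id, want$peak_idx))
  }
})

test_that("assigned-peak fraction is monotone in the maximum extension", {
  fx <- random_fixture(40, 400, 999)
  fracs <- vapply(c(1e4, 1e5, 5e5, 1e6), function(ext) {
    d <- create_regulatory_domains(fx$genes, fx$sizes, max_ext = ext)
    a <- assign_peaks(d, fx$peaks)
    1 - length(a$unassigned) / a$n_peaks
  }, 0)
  expect_true(all(diff(fracs) >= 0))
})
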