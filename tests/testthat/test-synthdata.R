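test_that("genome generation hits the target GC content and is reproducible", {
  cfg <- synth_config(n_chromosomes = 1, chrom_length = 1e6,
                      gc_content = 0.5, n_genes = 0, n_true_peaks = 0,
                      seed = 3)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  bases <- strsplit(g1[[1]], "")[[1]]
  expect_equal(mean(bases %in% c("G", "C")), 0.5, tolerance = 0.02)
  expect_error(generate_genome(synth_config(chrom_length = 0)),
               "positive")
})

test_that("gene models satisfy their structural invariants", {
  cfg <- synth_config(n_genes = 100, seed = 11)
  genes <- generate_gene_models(generate_genome(cfg), cfg)
  expect_equal(nrow(genes), 100)
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    expect_gte(length(es), 1)
    expect_true(all(es >= genes$start[i] & ee <= genes$end[i]))
    expect_true(all(ee > es))
    expect_true(genes$cds_start[i] >= genes$start[i])
    expect_true(genes$cds_end[i] <= genes$end[i])
  }
  ## roughly half the genes on each strand
  expect_gt(mean(genes$strand == "+"), 0.3)
  expect_lt(mean(genes$strand == "+"), 0.7)
  ## strand convention: TSS of a minus gene is its right end
  minus <- genes[genes$strand == "-", ][1, ]
  expect_equal(minus$tss, minus$end - 1)
  expect_equal(minus$tes, minus$start)
  expect_error(
    generate_gene_models(c(chr1 = 3e5),
                         synth_config(n_chromosomes = 1,
                                      chrom_length = 3e5, n_genes = 50)),
    "capacity")
})

test_that("planted peaks follow the configured category mix and length law", {
  cfg <- synth_config(category_props = c(intron = 1.0), n_true_peaks = 50,
                      seed = 5)
  genome <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
  genes <- generate_gene_models(genome, cfg)
  pl <- plant_enrichment(genome, genes, cfg)
  expect_equal(nrow(pl$peaks), 50)
  expect_true(all(pl$peaks$category == "intron"))

  cfg2 <- synth_config(n_true_peaks = 2000, n_chromosomes = 3,
                       chrom_length = 8e6, n_genes = 400,
                       peak_min_gap = 500, seed = 6)
  genome2 <- setNames(rep(8e6, 3), paste0("chr", 1:3))
  genes2 <- generate_gene_models(genome2, cfg2)
  pl2 <- plant_enrichment(genome2, genes2, cfg2)
  frac <- table(factor(pl2$peaks$category,
                       c(names(cfg2$category_props), "unlabeled"))) / 2000
  for (cat in names(cfg2$category_props)) {
    expect_lt(abs(frac[[cat]] - cfg2$category_props[[cat]]), 0.03)
  }
  lens <- pl2$peaks$end - pl2$peaks$start
  expect_equal(mean(lens), 692, tolerance = 0.1)
  ## every planted peak lies within its chromosome
  expect_true(all(pl2$peaks$start >= 0 & pl2$peaks$end <= 8e6))
  expect_error(
    plant_enrichment(genome, genes[0, ],
                     synth_config(category_props = c(intron = 1),
                                  n_true_peaks = 5)),
    "intron")
})

test_that("probe tracks carry the planted signal at the right probes", {
  cfg <- synth_config(enrich_mu = 2, noise_sigma = 0.5, seed = 8)
  genome <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
  genes <- generate_gene_models(genome, cfg)
  pl <- plant_enrichment(genome, genes, cfg)
  tr <- simulate_probe_track(genome, pl$peaks, cfg)
  ## positions strictly increasing at constant spacing per chromosome
  for (ch in unique(tr$chrom)) {
    d <- diff(tr$start[tr$chrom == ch])
    expect_true(all(d == cfg$probe_spacing))
  }
  mid <- tr$start + 25
  inpk <- rep(FALSE, nrow(tr))
  for (i in seq_len(nrow(pl$peaks))) {
    sel <- tr$chrom == pl$peaks$chrom[i] & mid >= pl$peaks$start[i] &
      mid < pl$peaks$end[i]
    inpk[sel] <- TRUE
  }
  expect_gte(sum(inpk), 400)
  expect_equal(mean(tr$ratio[inpk]), 2, tolerance = 0.05)
  ## null track
  tr0 <- simulate_probe_track(genome, pl$peaks[0, ], cfg)
  expect_lt(abs(mean(tr0$ratio)), 3 * 0.5 / sqrt(nrow(tr0)))
})

test_that("motif planting respects the plant rate and records placements", {
  cfg <- synth_config(n_true_peaks = 60, motif_plant_rate = 1.0, seed = 9)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  pl <- plant_enrichment(genome, genes, cfg)
  pm <- plant_motifs(genome, pl$peaks, DEFAULT_MOTIF, cfg)
  expect_true(all(pm$flags$planted))
  seqs <- extract_sequences(pm$genome, pl$peaks)
  hits <- scan_consensus(seqs, consensus_pattern(DEFAULT_MOTIF,
                                                 include_revcomp = TRUE))
  expect_true(all(hits$flags))
  ## the recorded offset points at the instance
  i <- which(pm$flags$strand == "+")[1]
  off <- pm$flags$offset[i]
  expect_equal(substr(seqs[i], off + 1, off + nchar(DEFAULT_MOTIF)),
               DEFAULT_MOTIF)
  cfg0 <- synth_config(n_true_peaks = 60, motif_plant_rate = 0, seed = 9)
  pm0 <- plant_motifs(genome, pl$peaks, DEFAULT_MOTIF, cfg0)
  expect_false(any(pm0$flags$planted))
  expect_identical(pm0$genome, genome)
})

test_that("expression table delivers the exact DE counts", {
  cfg <- synth_config(n_genes = 100, de_up = 26, de_down = 47, seed = 10)
  genes <- generate_gene_models(c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6), cfg)
  expr <- simulate_expression_and_de(genes, cfg)
  expect_equal(sum(expr$fold_change > 1.5), 26)
  expect_equal(sum(expr$fold_change < -1.5), 47)
  expect_equal(sum(abs(expr$fold_change) >= 1.5) , 73)
  expect_false(anyDuplicated(expr$expr) > 0)
  cfg0 <- synth_config(n_genes = 100, de_up = 0, de_down = 0, seed = 10)
  expr0 <- simulate_expression_and_de(genes, cfg0)
  expect_equal(sum(abs(expr0$fold_change) > 1.5), 0)
  expect_error(
    simulate_expression_and_de(genes, synth_config(n_genes = 100,
                                                   de_up = 60,
                                                   de_down = 60)),
    "exceeds")
})

test_that("DHS placement hits the co-occurrence rate at both extremes", {
  genome <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
  cfg1 <- synth_config(dhs_overlap_rate = 1, seed = 12)
  genes <- generate_gene_models(genome, cfg1)
  pl <- plant_enrichment(genome, genes, cfg1)
  d1 <- simulate_dhs(genome, pl$peaks, cfg1)
  expect_equal(dhs_cooccurrence(pl$peaks, d1$dhs)$fraction, 1.0)
  cfg0 <- synth_config(dhs_overlap_rate = 0, seed = 12)
  d0 <- simulate_dhs(genome, pl$peaks, cfg0)
  expect_equal(dhs_cooccurrence(pl$peaks, d0$dhs)$fraction, 0.0)
})

test_that("the whole study is byte-identical under a fixed seed", {
  cfg <- synth_config(n_true_peaks = 30, seed = 21)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$track, s2$track)
  expect_identical(s1$truth, s2$truth)
  ## truth ledger is complete: one row per planted peak, flags aligned
  expect_equal(nrow(s1$truth$peaks), 30)
  expect_setequal(s1$truth$peaks$peak_id, s1$peaks$peak_id)
  expect_true(all(c("category", "planted", "dhs") %in%
                    names(s1$truth$peaks)))
})
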