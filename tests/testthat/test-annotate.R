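## Two-gene fixture exercising every pairwise precedence conflict:
## gene A (+) on chr1 with CDS/exons/introns, gene B (+) downstream so
## that A's tail lies in B's promoter window, plus a minus-strand gene.
fixture_genes <- function() {
  a <- mk_gene("gA", "chr1", 20000, 50000, "+",
               exon_starts = list(c(20000, 30000, 44000)),
               exon_ends = list(c(24000, 34000, 50000)),
               cds_start = 22000, cds_end = 46000)
  b <- mk_gene("gB", "chr1", 58000, 80000, "+",
               exon_starts = list(c(58000, 70000)),
               exon_ends = list(c(62000, 80000)),
               cds_start = 59000, cds_end = 75000)
  m <- mk_gene("gM", "chr2", 40000, 60000, "-",
               exon_starts = list(c(40000, 52000)),
               exon_ends = list(c(45000, 60000)),
               cds_start = 42000, cds_end = 57000)
  mk_genes(a, b, m)
}

pk1 <- function(chrom, mid) {
  data.frame(chrom = chrom, start = mid - 50, end = mid + 50,
             peak_id = paste0("p", mid), stringsAsFactors = FALSE)
}

test_that("category assignment honors definitions and precedence", {
  genes <- fixture_genes()
  lens <- c(chr1 = 2e5, chr2 = 2e5)
  cat1 <- function(chrom, mid) {
    as.character(assign_category(pk1(chrom, mid), genes, lens))
  }
  expect_equal(cat1("chr1", 17000), "promoter")   # 3 kb upstream of gA
  expect_equal(cat1("chr1", 36000), "intron")     # intron 2 of gA
  expect_equal(cat1("chr1", 23000), "coding")     # CDS of gA
  expect_equal(cat1("chr1", 21000), "exon")       # exon 1 before CDS start
  expect_equal(cat1("chr1", 5000), "intergenic")
  ## CDS of gA within 10 kb upstream of gB's TSS -> promoter wins
  expect_equal(cat1("chr1", 49000), "promoter")
  ## just downstream of gA's TES but inside gB's promoter -> promoter
  expect_equal(cat1("chr1", 51000), "promoter")
  ## downstream of gB's TES -> tes
  expect_equal(cat1("chr1", 85000), "tes")
  ## minus-strand gene: promoter is at high coordinates
  expect_equal(cat1("chr2", 65000), "promoter")
  expect_equal(cat1("chr2", 35000), "tes")
  expect_equal(cat1("chr2", 48000), "intron")
  ## precedence is configurable: demoting promoter exposes the CDS
  expect_equal(as.character(
    assign_category(pk1("chr1", 45000), genes, lens,
                    precedence = c("tes", "coding", "exon", "intron",
                                   "promoter", "intergenic"))),
    "coding")
})

test_that("category summaries conserve counts and sum to 100", {
  genes <- fixture_genes()
  lens <- c(chr1 = 2e5, chr2 = 2e5)
  peaks <- do.call(rbind, lapply(c(17000, 36000, 23000, 5000, 85000),
                                 function(m) pk1("chr1", m)))
  s <- summarize_categories(peaks, genes, lens)
  expect_equal(sum(s$count), nrow(peaks))
  expect_equal(sum(s$percent), 100)
  all_inter <- summarize_categories(pk1("chr1", 5000), genes, lens)
  expect_equal(all_inter$percent[all_inter$category == "intergenic"], 100)
  expect_error(summarize_categories(peaks[0, ], genes, lens), "empty")
})

test_that("peak-gene links match the all-pairs oracle", {
  genes <- fixture_genes()
  ## one gene, one peak at its TSS
  g1 <- genes[genes$gene_id == "gA", ]
  at_tss <- pk1("chr1", 20000)
  res <- map_peaks_to_genes(at_tss, g1)
  expect_equal(nrow(res$links), 1)
  expect_equal(res$links$offset, 0)
  ## boundary: 10,001 bp upstream -> no link; 10,000 -> link
  expect_equal(nrow(map_peaks_to_genes(pk1("chr1", 9999), g1)$links), 0)
  expect_equal(nrow(map_peaks_to_genes(pk1("chr1", 10000), g1)$links), 1)
  ## randomized peaks vs quadratic oracle
  set.seed(9)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      start = sample.int(150000, 200),
                      stringsAsFactors = FALSE)
  peaks$end <- peaks$start + 100
  peaks$peak_id <- sprintf("p%03d", seq_len(200))
  got <- map_peaks_to_genes(peaks, genes)$links
  exp <- oracle_links(peaks, genes)
  exp <- exp[order(exp$peak_id, exp$gene_id), ]
  rownames(exp) <- NULL
  expect_equal(got, exp)
  expect_equal(map_peaks_to_genes(peaks, genes)$n_genes,
               length(unique(exp$gene_id)))
  expect_error(map_peaks_to_genes(peaks, genes, window = 0), "positive")
})

test_that("links are symmetric under genome reflection with strand flip", {
  genes <- fixture_genes()
  L <- 2e5
  set.seed(10)
  peaks <- data.frame(chrom = "chr1", start = sample.int(L - 200, 100))
  peaks$end <- peaks$start + 100
  peaks$peak_id <- sprintf("p%03d", seq_len(100))
  fwd <- map_peaks_to_genes(peaks, genes)$links
  ## reflect chr1: x -> L - x, flip strands
  rg <- genes[genes$chrom == "chr1", ]
  refl <- do.call(rbind, lapply(seq_len(nrow(rg)), function(i) {
    mk_gene(rg$gene_id[i], "chr1", L - rg$end[i], L - rg$start[i],
            ifelse(rg$strand[i] == "+", "-", "+"),
            exon_starts = list(rev(L - rg$exon_ends[[i]])),
            exon_ends = list(rev(L - rg$exon_starts[[i]])),
            cds_start = L - rg$cds_end[i], cds_end = L - rg$cds_start[i])
  }))
  rpeaks <- data.frame(chrom = "chr1", start = L - peaks$end,
                       end = L - peaks$start, peak_id = peaks$peak_id)
  rev_links <- map_peaks_to_genes(rpeaks, refl)$links
  m <- merge(fwd, rev_links, by = c("peak_id", "gene_id"))
  expect_equal(nrow(m), nrow(fwd))
  expect_equal(nrow(rev_links), nrow(fwd))
  ## reflection moves each midpoint by one base (floor), never more
  expect_true(all(abs(m$offset.x - m$offset.y) <= 1))
})

test_that("density track arithmetic and conservation hold", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(rep(100, 8), 1.5e6), end = c(rep(200, 8),
                                                             1.5e6 + 100))
  d <- density_track(peaks, c(chr1 = 2e6), bin = 1e6)
  expect_equal(d$log2_density[1], log2(9))
  expect_equal(d$count[2], 1)
  expect_equal(sum(d$count), nrow(peaks))
  empty <- density_track(peaks[0, ], c(chr1 = 2e6), bin = 1e6)
  expect_true(all(empty$log2_density == 0))
  expect_error(density_track(peaks, c(chr1 = 2e6), bin = 0), "positive")
})

test_that("gene-peak density correlation behaves at its extremes", {
  genes <- fixture_genes()
  lens <- c(chr1 = 2e5, chr2 = 2e5)
  ## peaks exactly at gene midpoints -> counts identical -> cor 1
  gp <- data.frame(chrom = genes$chrom,
                   start = floor((genes$start + genes$end) / 2) - 50)
  gp$end <- gp$start + 100
  expect_equal(gene_peak_density_correlation(gp, genes, lens, bin = 5e4),
               1.0)
  ## all peaks in one far-away bin -> zero gene variance case is NA
  lone <- data.frame(chrom = "chr1", start = rep(1000, 5),
                     end = rep(1100, 5))
  empty_genes <- genes[0, ]
  expect_warning(
    v <- gene_peak_density_correlation(lone, empty_genes, lens, bin = 5e4),
    "zero-variance")
  expect_true(is.na(v))
})

test_that("gene-planted peaks track gene density; uniform peaks do not", {
  ## genes confined to chr1 give the genome a gene-density contrast
  cfg <- synth_config(n_chromosomes = 1, n_genes = 30,
                      n_true_peaks = 150,
                      category_props = c(intron = 0.5, coding = 0.25,
                                         exon = 0.25),
                      seed = 14)
  lens <- c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6)
  genes <- generate_gene_models(c(chr1 = 2e6), cfg)
  pl <- plant_enrichment(c(chr1 = 2e6), genes, cfg)
  expect_gt(gene_peak_density_correlation(pl$peaks, genes, lens,
                                          bin = 2e5), 0.5)
  ## uniform peaks over the whole genome: correlation near zero
  cors <- vapply(1:10, function(sd) {
    set.seed(1000 + sd)
    up <- data.frame(chrom = sample(names(lens), 150, TRUE),
                     start = sample.int(2e6 - 200, 150))
    up$end <- up$start + 200
    gene_peak_density_correlation(up, genes, lens, bin = 2e5)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.3)
})
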