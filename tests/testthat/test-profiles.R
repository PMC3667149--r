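test_that("expression strata split 30/40/30 with deterministic ties", {
  expr <- data.frame(gene_id = sprintf("g%02d", 1:10), expr = 10:1)
  gr <- tertile_split(expr)
  expect_length(gr$top30, 3)
  expect_length(gr$middle40, 4)
  expect_length(gr$bottom30, 3)
  expect_equal(gr$top30, c("g01", "g02", "g03"))
  ## all values equal: split purely by id order, same sizes
  tie <- data.frame(gene_id = sprintf("g%02d", 10:1), expr = rep(1, 10))
  gt <- tertile_split(tie)
  expect_equal(gt$top30, c("g01", "g02", "g03"))
  expect_length(gt$middle40, 4)
  ## partition invariant
  expect_setequal(unlist(gr), expr$gene_id)
  expect_equal(anyDuplicated(unlist(gr)), 0)
  expect_error(tertile_split(expr, c(0.5, 0.4, 0.2)), "sum to 1")
})

test_that("TSS metaprofiles bin strand-oriented offsets", {
  gp <- mk_gene("gp", "chr1", 50000, 70000, "+")
  pk <- data.frame(chrom = "chr1", start = 50150 - 50, end = 50150 + 50)
  prof <- tss_metaprofile(pk, gp, window = 10000, bin = 200)
  expect_equal(prof$count[prof$bin_start == 0], 1)
  expect_equal(sum(prof$count), 1)
  ## minus-strand gene, peak 150 bp downstream (lower coordinate)
  gm <- mk_gene("gm", "chr1", 50000, 70000, "-")
  pkm <- data.frame(chrom = "chr1", start = gm$tss - 150 - 50,
                    end = gm$tss - 150 + 50)
  profm <- tss_metaprofile(pkm, gm, window = 10000, bin = 200)
  expect_equal(profm$count[profm$bin_start == 0], 1)
  expect_equal(prof$density[prof$bin_start == 0], 1)
  expect_error(tss_metaprofile(pk, gp, window = 10000, bin = 300),
               "divide")
})

test_that("metaprofile counts are conserved and double-count close genes", {
  ## two genes whose windows overlap: one peak contributes to both
  g1 <- mk_gene("a", "chr1", 50000, 80000, "+")
  g2 <- mk_gene("b", "chr1", 55000, 90000, "+")
  genes <- mk_genes(g1, g2)
  pk <- data.frame(chrom = "chr1", start = 52400, end = 52600)
  prof <- tss_metaprofile(pk, genes, window = 10000, bin = 200)
  expect_equal(sum(prof$count), 2)
  expect_equal(prof$density[prof$count > 0], c(1, 1) / 2)
  ## relabeling genes leaves the profile unchanged
  genes2 <- genes
  genes2$gene_id <- c("x", "y")
  prof2 <- tss_metaprofile(pk, genes2, window = 10000, bin = 200)
  expect_equal(prof2$count, prof$count)
})

test_that("profiles are invariant under genome reflection with strand flip", {
  ## reflect every coordinate (x -> L - 1 - x) and flip strands: the
  ## relative peak/TSS geometry is unchanged, so the profile must be too
  set.seed(23)
  L <- 2e5
  genes <- mk_genes(mk_gene("a", "chr1", 50000, 90000, "+"),
                    mk_gene("b", "chr1", 120000, 160000, "-"))
  mids <- sample.int(L - 2, 300)
  pk <- data.frame(chrom = "chr1", start = mids, end = mids + 1)
  fwd <- tss_metaprofile(pk, genes, window = 10000, bin = 200)
  refl <- mk_genes(mk_gene("a", "chr1", L - 90000, L - 50000, "-"),
                   mk_gene("b", "chr1", L - 160000, L - 120000, "+"))
  rpk <- data.frame(chrom = "chr1", start = L - pk$end, end = L - pk$start)
  rev <- tss_metaprofile(rpk, refl, window = 10000, bin = 200)
  expect_equal(rev$count, fwd$count)
})

test_that("DE intersection counts each linked gene once, monotonically", {
  links <- data.frame(peak_id = c("p1", "p2", "p3", "p4"),
                      gene_id = c("g1", "g1", "g2", "g3"))
  expr <- data.frame(gene_id = c("g1", "g2", "g3"),
                     fold_change = c(2.0, -1.7, 1.2))
  de <- intersect_de_genes(links, expr)
  expect_equal(de$up, "g1")
  expect_equal(de$down, "g2")
  ## monotone non-increasing in the threshold
  sizes <- vapply(c(1.5, 1.8, 2.5), function(th) {
    d <- intersect_de_genes(links, expr, th)
    length(d$up) + length(d$down)
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(lengths(intersect_de_genes(links, expr, Inf)),
               c(up = 0, down = 0))
  none <- intersect_de_genes(links[0, ], expr)
  expect_length(none$up, 0)
  ## missing fold change: warn and skip
  expr2 <- expr[-1, ]
  expect_warning(de2 <- intersect_de_genes(links, expr2), "missing")
  expect_length(de2$up, 0)
})

test_that("DHS co-occurrence respects the half-open margin boundary", {
  pk <- data.frame(chrom = "chr1", start = 5000, end = 5500)
  ## DHS beginning at the last flagged base
  at_edge <- data.frame(chrom = "chr1", start = 6499, end = 6699)
  expect_equal(dhs_cooccurrence(pk, at_edge, 1000)$fraction, 1)
  past_edge <- data.frame(chrom = "chr1", start = 6500, end = 6700)
  expect_equal(dhs_cooccurrence(pk, past_edge, 1000)$fraction, 0)
  left_edge <- data.frame(chrom = "chr1", start = 3900, end = 4000)
  expect_equal(dhs_cooccurrence(pk, left_edge, 1000)$fraction, 0)
  left_in <- data.frame(chrom = "chr1", start = 3900, end = 4001)
  expect_equal(dhs_cooccurrence(pk, left_in, 1000)$fraction, 1)
  expect_error(dhs_cooccurrence(pk, at_edge, -1), ">= 0")
})

test_that("DHS co-occurrence equals the quadratic all-pairs oracle", {
  set.seed(24)
  pk <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                   start = sample.int(5e5, 300))
  pk$end <- pk$start + sample(200:800, 300, TRUE)
  dhs <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                    start = sample.int(5e5, 300))
  dhs$end <- dhs$start + 150
  got <- dhs_cooccurrence(pk, dhs, 1000)
  exp_flags <- vapply(seq_len(nrow(pk)), function(i) {
    any(dhs$chrom == pk$chrom[i] &
          dhs$start < pk$end[i] + 1000 &
          dhs$end > pk$start[i] - 1000)
  }, logical(1))
  expect_equal(got$flags, exp_flags)
  expect_equal(got$fraction, mean(exp_flags))
})

test_that("TSS-depleted placement yields a V-shaped profile", {
  ## deplete peaks within +/-1 kb of TSS, enrich the flanks
  set.seed(25)
  genes <- do.call(rbind, lapply(1:40, function(i) {
    mk_gene(sprintf("g%02d", i), "chr1", i * 40000, i * 40000 + 20000,
            sample(c("+", "-"), 1))
  }))
  offs <- sample(c(-1, 1), 2000, TRUE) * sample(1000:9999, 2000, TRUE)
  gi <- sample.int(40, 2000, TRUE)
  mid <- ifelse(genes$strand[gi] == "+", genes$tss[gi] + offs,
                genes$tss[gi] - offs)
  pk <- data.frame(chrom = "chr1", start = mid - 100, end = mid + 100)
  prof <- tss_metaprofile(pk, genes, window = 10000, bin = 200)
  min_bin <- prof$bin_start[which.min(prof$count)]
  expect_lte(abs(min_bin + 100), 1000)
})
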