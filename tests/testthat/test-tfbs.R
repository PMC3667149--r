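CTCF <- "AG[GA][GT]GG[CAT][GAT][CG]"

test_that("match scores hit their definitional extremes and the formula", {
  x <- pwm_from_consensus("ACGTACGTAC", identity = 0.8)
  cons <- pwm_consensus(x)
  expect_equal(match_score(x, cons), 1.0)
  ## column-wise argmin word
  worst <- paste(c("A", "C", "G", "T")[apply(x$counts, 2, which.min)],
                 collapse = "")
  expect_equal(match_score(x, worst), 0.0)
  expect_true(is.na(match_score(x, "ACGTNCGTAC")))
  expect_error(match_score(x, "ACGT"), "width")
  ## random PWM / window pairs vs the independent formula recomputation
  set.seed(15)
  for (i in 1:25) {
    counts <- matrix(rexp(4 * 8) + 0.01, 4, 8)
    y <- pwm(counts, id = "r")
    win <- rand_dna(1, 8)
    expect_equal(match_score(y, win), oracle_match_score(y, win),
                 tolerance = 1e-12)
  }
})

test_that("pwm scanning finds planted sites and is strand symmetric", {
  x <- pwm_from_consensus("ACGTACGTAC", identity = 0.9)
  cons <- pwm_consensus(x)
  set.seed(16)
  s <- rand_dna(1, 200)
  substr(s, 38, 47) <- cons
  hits <- scan_pwm(s, x, threshold = 0.95)
  expect_true(any(hits$offset == 37 & hits$score > 1 - 1e-9 &
                    hits$strand == "+"))
  expect_equal(nrow(scan_pwm(s, x, 0.85)),
               nrow(scan_pwm(revcomp(s), x, 0.85)))
  ## quadratic all-windows oracle on a 1 kb sequence
  s2 <- rand_dna(1, 1000)
  got <- scan_pwm(s2, x, threshold = 0.8, both_strands = TRUE)
  exp_fwd <- vapply(1:(1000 - 9), function(o) {
    oracle_match_score(x, substr(s2, o, o + 9))
  }, numeric(1))
  rc2 <- revcomp(s2)
  exp_rev <- vapply(1:(1000 - 9), function(o) {
    oracle_match_score(x, substr(rc2, o, o + 9))
  }, numeric(1))
  ## a minus-strand hit at rc offset o maps to forward offset L - w - o
  exp_hits <- sort(c(which(exp_fwd >= 0.8) - 1,
                     1000 - 10 - (which(exp_rev >= 0.8) - 1)))
  expect_equal(sort(got$offset), exp_hits)
})

test_that("controls preserve peak length and chromosome, avoid peaks", {
  set.seed(17)
  peaks <- data.frame(chrom = rep(c("chr1", "chr2"), 25),
                      start = sample.int(9e4, 50))
  peaks$end <- peaks$start + sample(200:900, 50, TRUE)
  lens <- c(chr1 = 1e5, chr2 = 1e5)
  ctrls <- sample_controls(peaks, lens, n_sets = 10, seed = 18)
  expect_length(ctrls, 10)
  for (cs in ctrls) {
    expect_equal(cs$end - cs$start, peaks$end - peaks$start)
    expect_equal(cs$chrom, peaks$chrom)
    for (i in seq_len(nrow(cs))) {
      same <- peaks$chrom == cs$chrom[i]
      expect_false(any(cs$start[i] < peaks$end[same] &
                         cs$end[i] > peaks$start[same]))
    }
  }
  ## deterministic under a fixed seed
  again <- sample_controls(peaks, lens, n_sets = 10, seed = 18)
  expect_identical(ctrls, again)
  expect_error(sample_controls(data.frame(chrom = "chr1", start = 0,
                                          end = 2e5), lens),
               "longer than its chromosome")
})

test_that("control GC matches the genome background", {
  cfg <- synth_config(seed = 19, gc_content = 0.41)
  genome <- generate_genome(cfg)
  genes <- generate_gene_models(genome, cfg)
  pl <- plant_enrichment(genome, genes, cfg)
  ctrl <- sample_controls(pl$peaks, genome, n_sets = 2, seed = 20)[[1]]
  seqs <- extract_sequences(genome, ctrl)
  gc <- mean(strsplit(paste(seqs, collapse = ""), "")[[1]] %in% c("G", "C"))
  n <- sum(nchar(seqs))
  expect_lt(abs(gc - 0.41), 4 * sqrt(0.41 * 0.59 / n))
})

test_that("chi-square enrichment separates planted from null signals", {
  ## O = E gives chi2 0, p ~ 1
  x <- pwm_from_consensus("ACGTACGTAC")
  set.seed(21)
  seqs <- rand_dna(20, 300)
  same <- list(seqs, seqs)
  res <- chi_square_enrichment(seqs, same, list(x), threshold = 0.9)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)
  expect_false(res$significant)
  ## p decreases as |O - E| grows at fixed E
  p_at <- function(O, E) pchisq((O - E)^2 / E, 1, lower.tail = FALSE)
  expect_true(all(diff(p_at(c(10, 14, 20, 30), 10)) < 0))
  expect_error(chi_square_enrichment(seqs, same, list(), 0.9), "empty")
  expect_error(chi_square_enrichment(seqs, list(), list(x), 0.9),
               "control")
})

test_that("the CTCF pattern expands to 72 forward words and scans exactly", {
  pat <- consensus_pattern(CTCF, include_revcomp = TRUE)
  expect_equal(pat$width, 9)
  fwd <- expand_consensus(pat)
  expect_length(fwd, 72)
  expect_length(unique(fwd), 72)
  both <- expand_consensus(pat, with_revcomp = TRUE)
  expect_lte(length(both), 144)
  expect_equal(length(both), 144)  # no palindromic overlap here
  expect_equal(pat$iupac, "AGRKGGHDS")
  ## planted expansion word counted once
  s <- paste0(strrep("T", 30), "AGGTGGAGC", strrep("T", 30))
  expect_equal(scan_consensus(s, pat)$counts, 1)
  ## regex oracle on random 2 kb sequences
  set.seed(22)
  seqs <- rand_dna(30, 2000)
  got <- scan_consensus(seqs, pat)
  expect_equal(got$counts, oracle_consensus_counts(seqs, CTCF, TRUE))
  ## strand symmetry of counts
  expect_equal(scan_consensus(revcomp(seqs), pat)$counts, got$counts)
  ## malformed patterns are rejected with a position
  expect_error(consensus_pattern("AG[GA"), "unclosed")
  expect_error(consensus_pattern("AG]GA"), "unmatched")
  expect_error(consensus_pattern("AX[GA]"), "invalid base")
})

test_that("N-containing windows never match pattern or PWM scans", {
  pat <- consensus_pattern("AGGTGGAGC", include_revcomp = FALSE)
  expect_equal(scan_consensus("TTAGGTGGAGCTT", pat)$counts, 1)
  expect_equal(scan_consensus("TTAGGTGNAGCTT", pat)$counts, 0)
  x <- pwm_from_consensus("AGGTGGAGC")
  expect_equal(nrow(scan_pwm("TTAGGTGNAGCTT", x, threshold = 0.5)), 0)
})
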