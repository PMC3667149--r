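#' Plant enriched regions by target feature category
#'
#' Peak counts per category follow the configured proportions (by
#' largest-remainder apportionment); any mass missing from 1 becomes an
#' "unlabeled" remainder placed in a uniformly chosen feature category.
#' Each peak's midpoint is drawn uniformly from the per-base mask of its
#' target category (the same masks [assign_category()] uses, so labels
#' are recovered exactly); lengths follow a shifted geometric law with
#' minimum `2 * probe_spacing` and the configured mean. Peaks are kept
#' at least `peak_min_gap` bp apart.
#'
#' @param genome named character vector of sequences or named lengths.
#' @param genes gene-model data.frame.
#' @param config a [synth_config()].
#' @return list with `peaks` (peak_id, chrom, start, end, category) and
#'   `truth` (the same table; downstream generator stages append motif,
#'   DHS and DE columns to the study-level truth ledger).
#' @export
plant_enrichment <- function(genome, genes, config) {
  stopifnot(inherits(config, "synth_config"))
  lens <- chrom_lengths(genome)
  props <- config$category_props
  p_unlab <- 1 - sum(props)
  n <- config$n_true_peaks
  counts <- apportion(n, c(props, unlabeled = p_unlab))
  labels <- rep(c(names(props), "unlabeled"), counts)
  masks <- category_masks(genes, lens)
  min_len <- 2 * config$probe_spacing
  if (config$peak_length_mean < min_len) {
    stop("peak_length_mean must be >= 2 * probe_spacing for planted peaks")
  }
  ## flatten masks for weighted uniform sampling of a base per category
  flat <- list()
  for (cat in FEATURE_CATEGORIES) {
    per_ch <- lapply(names(lens), function(ch) masks[[ch]][[cat]])
    w <- vapply(per_ch, function(m) sum(IRanges::width(m)), numeric(1))
    flat[[cat]] <- list(chroms = names(lens), ranges = per_ch, w = w)
  }
  sample_base <- function(cat) {
    fl <- flat[[cat]]
    tot <- sum(fl$w)
    if (tot == 0) stop("no genomic bases available for category '", cat, "'")
    ci <- sample.int(length(fl$w), 1, prob = fl$w / tot)
    m <- fl$ranges[[ci]]
    off <- sample.int(fl$w[ci], 1)  # 1-based offset into the mask bases
    cw <- cumsum(IRanges::width(m))
    k <- which(cw >= off)[1]
    prev <- if (k > 1) cw[k - 1] else 0
    pos0 <- (IRanges::start(m)[k] - 1) + (off - prev - 1)
    list(chrom = fl$chroms[ci], mid = pos0)
  }
  with_seed_if(derive_seed(config$seed, "peaks"), {
    labels <- sample(labels)  # shuffle placement order
    placed <- lapply(names(lens), function(ch) NULL)
    names(placed) <- names(lens)
    res <- vector("list", n)
    for (i in seq_len(n)) {
      cat_i <- labels[i]
      target <- if (cat_i == "unlabeled") {
        ok <- Filter(function(cc) sum(flat[[cc]]$w) > 0, FEATURE_CATEGORIES)
        ok[sample.int(length(ok), 1)]
      } else cat_i
      for (try in seq_len(2000)) {
        len <- min_len + rgeom(1, 1 / (config$peak_length_mean - min_len + 1))
        bp <- sample_base(target)
        s <- bp$mid - floor(len / 2); e <- s + len
        if (s < 0 || e > lens[[bp$chrom]]) next
        prev <- placed[[bp$chrom]]
        if (!is.null(prev) &&
            any(s - config$peak_min_gap < prev[, 2] &
                e + config$peak_min_gap > prev[, 1])) next
        placed[[bp$chrom]] <- rbind(prev, c(s, e))
        res[[i]] <- list(chrom = bp$chrom, start = s, end = e,
                         category = cat_i)
        break
      }
      if (is.null(res[[i]])) {
        stop("could not place peak ", i, " (category '", cat_i,
             "'); genome too crowded")
      }
    }
    peaks <- data.frame(
      chrom = vapply(res, `[[`, character(1), "chrom"),
      start = vapply(res, `[[`, numeric(1), "start"),
      end = vapply(res, `[[`, numeric(1), "end"),
      category = vapply(res, `[[`, character(1), "category"),
      stringsAsFactors = FALSE
    )
    peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
    peaks$peak_id <- sprintf("truepeak%05d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    peaks <- peaks[, c("peak_id", "chrom", "start", "end", "category")]
    list(peaks = peaks, truth = peaks)
  })
}

#' Simulate a tiling-array probe track
#'
#' Probes start every `probe_spacing` bp; the log2 ratio is
#' Normal(0, noise_sigma) for background probes and
#' Normal(enrich_mu, noise_sigma) for probes whose midpoint (probe start
#' + probe_length / 2) falls inside a planted peak.
#'
#' @param genome named character vector of sequences or named lengths.
#' @param true_peaks planted-peak data.frame (chrom, start, end).
#' @param config a [synth_config()].
#' @return probe-track data.frame (chrom, start, ratio) with the probe
#'   spacing attached as attribute `spacing`.
#' @export
simulate_probe_track <- function(genome, true_peaks, config) {
  stopifnot(inherits(config, "synth_config"))
  lens <- chrom_lengths(genome)
  sp <- config$probe_spacing
  with_seed_if(derive_seed(config$seed, "probes"), {
    out <- lapply(names(lens), function(ch) {
      starts <- seq(0, lens[[ch]] - config$probe_length, by = sp)
      r <- rnorm(length(starts), 0, config$noise_sigma)
      pk <- true_peaks[true_peaks$chrom == ch, , drop = FALSE]
      if (nrow(pk)) {
        mid <- starts + floor(config$probe_length / 2)
        pts <- to_iranges(mid, mid + 1)
        inpk <- IRanges::overlapsAny(pts, to_iranges(pk$start, pk$end))
        r[inpk] <- rnorm(sum(inpk), config$enrich_mu, config$noise_sigma)
      }
      data.frame(chrom = ch, start = starts, ratio = r,
                 stringsAsFactors = FALSE)
    })
    track <- do.call(rbind, out)
    attr(track, "spacing") <- sp
    track
  })
}

#' Plant motif instances into peak sequences
#'
#' For each planted peak, with probability `motif_plant_rate`, a motif
#' instance is written over the genome at a uniformly chosen offset
#' within the peak on a uniformly chosen strand. The motif may be a
#' consensus string (planted verbatim) or a [pwm()] (an instance is
#' sampled column-wise from its frequencies). Peaks shorter than the
#' motif are skipped with a warning and flagged FALSE.
#'
#' @param genome named character vector of sequences (modified copy is
#'   returned).
#' @param true_peaks planted-peak data.frame.
#' @param motif consensus string or `pwm`.
#' @param config a [synth_config()].
#' @return list with `genome` (sequences with motifs planted) and
#'   `flags` (peak_id, planted, offset, strand).
#' @export
plant_motifs <- function(genome, true_peaks, motif, config) {
  stopifnot(inherits(config, "synth_config"), is.character(genome))
  w <- if (inherits(motif, "pwm")) motif$width else nchar(motif)
  freq <- if (inherits(motif, "pwm")) pwm_freq(motif) else NULL
  rate <- config$motif_plant_rate
  n <- nrow(true_peaks)
  flags <- data.frame(peak_id = true_peaks$peak_id,
                      planted = FALSE, offset = NA_real_,
                      strand = NA_character_, stringsAsFactors = FALSE)
  with_seed_if(derive_seed(config$seed, "motifs"), {
    for (i in seq_len(n)) {
      len <- true_peaks$end[i] - true_peaks$start[i]
      if (len < w) {
        warning("peak ", true_peaks$peak_id[i], " shorter than motif; skipped")
        next
      }
      if (runif(1) >= rate) next
      off <- sample.int(len - w + 1, 1) - 1
      strand <- sample(c("+", "-"), 1)
      inst <- if (is.null(freq)) toupper(motif) else
        paste(apply(freq, 2, function(p) sample(BASES, 1, prob = p)),
              collapse = "")
      if (strand == "-") inst <- revcomp(inst)
      ch <- true_peaks$chrom[i]
      s <- true_peaks$start[i] + off  # 0-based genome offset
      substr(genome[[ch]], s + 1, s + w) <- inst
      flags$planted[i] <- TRUE
      flags$offset[i] <- off
      flags$strand[i] <- strand
    }
    list(genome = genome, flags = flags)
  })
}
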