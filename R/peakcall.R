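#' Peak-calling parameters (cutoff-ladder sliding-window detection)
#'
#' Defaults reproduce the printed tiling-array parameterization: the
#' cutoff ladder starts at 90% of the hypothetical maximum and descends
#' in 76 steps of 1%; a region qualifies with >= 4 above-cutoff probes
#' in a 500 bp sliding window, or with >= 2 consecutive above-cutoff
#' probes when every probe in the stretch is above the cutoff; peaks
#' are reported at a permutation-estimated FDR < 0.005.
#'
#' @param p_start ladder start, percent of the hypothetical maximum.
#' @param p_step ladder decrement in percent.
#' @param n_steps number of ladder rungs.
#' @param min_probes probes above cutoff required within `window` bp.
#' @param min_probes_all_above probes sufficing when all consecutive
#'   probes in the stretch are above the cutoff.
#' @param window sliding-window width (bp); above-cutoff probes closer
#'   than this are merged into one candidate region.
#' @param fdr_max strict FDR threshold for [filter_peaks()].
#' @param n_permutations ratio-shuffling permutations for
#'   [estimate_fdr()].
#' @param hypmax_k sigma multiplier in [hypothetical_maximum()].
#' @param spacing probe spacing in bp (NULL: inferred per chromosome).
#' @param seed seed for the permutation RNG.
#' @return an object of class `peak_params`.
#' @export
peak_params <- function(p_start = 90, p_step = 1, n_steps = 76,
                        min_probes = 4, min_probes_all_above = 2,
                        window = 500, fdr_max = 0.005,
                        n_permutations = 20, hypmax_k = 6,
                        spacing = NULL, seed = 1L) {
  if (p_start - p_step * (n_steps - 1) <= 0) {
    stop("ladder would reach a non-positive percentage")
  }
  if (min_probes_all_above > min_probes) {
    stop("min_probes_all_above must be <= min_probes")
  }
  if (window < 1) stop("window must be >= 1")
  if (fdr_max <= 0 || fdr_max > 1) stop("fdr_max must lie in (0, 1]")
  structure(list(p_start = p_start, p_step = p_step, n_steps = n_steps,
                 min_probes = min_probes,
                 min_probes_all_above = min_probes_all_above,
                 window = window, fdr_max = fdr_max,
                 n_permutations = n_permutations, hypmax_k = hypmax_k,
                 spacing = spacing, seed = as.integer(seed)),
            class = "peak_params")
}

#' Hypothetical maximum of a ratio track
#'
#' Scaling anchor for the cutoff ladder: mean + k standard deviations
#' (population) of the chromosome's log2 ratios.
#'
#' @param ratios numeric log2 ratios (>= 2 values).
#' @param k sigma multiplier.
#' @return scalar, in log2-ratio units.
#' @export
hypothetical_maximum <- function(ratios, k = 6) {
  if (length(ratios) < 2) stop("need at least 2 probes")
  mean(ratios) + k * pop_sd(ratios)
}

#' Descending ladder of absolute cutoffs
#'
#' @param params a [peak_params()].
#' @param hypmax the [hypothetical_maximum()] of the track.
#' @return numeric vector of absolute cutoffs, one per rung, descending;
#'   the rung percentages are attached as attribute `percent`.
#' @export
cutoff_ladder <- function(params, hypmax) {
  pct <- params$p_start - params$p_step * (seq_len(params$n_steps) - 1)
  if (any(pct <= 0)) stop("non-positive ladder percentage")
  structure(pct / 100 * hypmax, percent = pct)
}

## spacing of a per-chromosome probe table, honoring params$spacing,
## the generator's attribute, or the modal gap, in that order.
infer_spacing <- function(pos, params, track_attr = NULL) {
  if (!is.null(params$spacing)) return(params$spacing)
  if (!is.null(track_attr)) return(track_attr)
  if (length(pos) < 2) return(1)
  d <- diff(pos)
  as.numeric(names(sort(table(d), decreasing = TRUE))[1])
}

#' Candidate enriched regions at one absolute cutoff
#'
#' A maximal cluster of above-cutoff probes (consecutive gaps <=
#' `window` bp) qualifies when some `min_probes` of them fall within a
#' `window` bp window, or when >= `min_probes_all_above` consecutive
#' track probes are all above the cutoff with no below-cutoff probe in
#' between. The reported interval spans the first above-cutoff probe
#' start to the last above-cutoff probe start plus one probe spacing.
#'
#' @param track probe-track data.frame (chrom, start, ratio), sorted.
#' @param cutoff absolute log2-ratio cutoff.
#' @param params a [peak_params()].
#' @return data.frame (chrom, start, end) of qualifying regions.
#' @export
call_peaks_at_cutoff <- function(track, cutoff, params = peak_params()) {
  stop_if_not_df(track, c("chrom", "start", "ratio"), "track")
  sp_attr <- attr(track, "spacing")
  out <- lapply(unique(track$chrom), function(ch) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    o <- order(sub$start)
    pos <- sub$start[o]; r <- sub$ratio[o]
    m <- cpp_regions_at_cutoff(pos, r, cutoff, params$window,
                               params$min_probes,
                               params$min_probes_all_above)
    if (!nrow(m)) return(NULL)
    sp <- infer_spacing(pos, params, sp_attr)
    data.frame(chrom = ch, start = m[, 1], end = m[, 2] + sp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  }
  sort_intervals(out)
}

#' Call scored peaks down the cutoff ladder
#'
#' Runs [call_peaks_at_cutoff()] from the highest rung down; each peak's
#' score is the highest rung percentage at which any sub-region of it
#' qualifies, and overlapping regions from lower rungs extend a peak's
#' boundaries while keeping the higher score. The per-chromosome ladder
#' is anchored at that chromosome's hypothetical maximum (a single
#' genome-wide anchor is available via `global_ladder`).
#'
#' @param track probe-track data.frame (chrom, start, ratio).
#' @param params a [peak_params()].
#' @param global_ladder anchor the ladder at the genome-wide
#'   hypothetical maximum instead of per chromosome.
#' @return peak data.frame (chrom, start, end, score, n_probes,
#'   mean_ratio), disjoint and sorted; rung percentages and the anchors
#'   used are attached as attributes.
#' @export
call_peaks <- function(track, params = peak_params(),
                       global_ladder = FALSE) {
  stop_if_not_df(track, c("chrom", "start", "ratio"), "track")
  sp_attr <- attr(track, "spacing")
  hyp_global <- if (global_ladder) {
    hypothetical_maximum(track$ratio, params$hypmax_k)
  } else NULL
  chroms <- unique(track$chrom)
  anchors <- setNames(numeric(length(chroms)), chroms)
  res <- lapply(chroms, function(ch) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    o <- order(sub$start)
    pos <- sub$start[o]; r <- sub$ratio[o]
    hyp <- if (global_ladder) hyp_global else
      hypothetical_maximum(r, params$hypmax_k)
    anchors[ch] <<- hyp
    ladder <- cutoff_ladder(params, hyp)
    pct <- attr(ladder, "percent")
    sp <- infer_spacing(pos, params, sp_attr)
    ## accumulate scored regions rung by rung, merging on overlap
    cur <- NULL  # matrix: start, end, score
    for (i in seq_along(ladder)) {
      m <- cpp_regions_at_cutoff(pos, r, ladder[i], params$window,
                                 params$min_probes,
                                 params$min_probes_all_above)
      if (!nrow(m)) next
      reg <- cbind(m[, 1], m[, 2] + sp, pct[i])
      cur <- if (is.null(cur)) reg else rbind(cur, reg)
      ## merge overlapping intervals, keep max score per component
      o2 <- order(cur[, 1])
      cur <- cur[o2, , drop = FALSE]
      grp <- cumsum(c(1, cur[-1, 1] >= cummax(cur[-nrow(cur), 2])))
      if (nrow(cur) > 1) {
        cur <- cbind(tapply(cur[, 1], grp, min),
                     tapply(cur[, 2], grp, max),
                     tapply(cur[, 3], grp, max))
      }
    }
    if (is.null(cur)) return(NULL)
    cur <- matrix(cur, ncol = 3)
    ## per-peak probe stats at the peak's own score cutoff
    n_probes <- integer(nrow(cur)); mean_ratio <- numeric(nrow(cur))
    for (j in seq_len(nrow(cur))) {
      inpk <- pos >= cur[j, 1] & pos < cur[j, 2]
      n_probes[j] <- sum(inpk & r > cur[j, 3] / 100 * hyp)
      mean_ratio[j] <- mean(r[inpk])
    }
    data.frame(chrom = ch, start = cur[, 1], end = cur[, 2],
               score = cur[, 3], n_probes = n_probes,
               mean_ratio = mean_ratio, stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, res)
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0), score = numeric(0),
                        n_probes = integer(0), mean_ratio = numeric(0),
                        stringsAsFactors = FALSE)
  }
  peaks <- sort_intervals(peaks)
  rownames(peaks) <- NULL
  attr(peaks, "percent") <- params$p_start -
    params$p_step * (seq_len(params$n_steps) - 1)
  attr(peaks, "anchors") <- anchors
  peaks
}

#' Permutation-estimated FDR for called peaks
#'
#' For each of `n_permutations` random shuffles of the ratio values over
#' the fixed probe positions (per chromosome), peaks are re-called down
#' the same ladder. Pooling genome-wide, FDR(score s) = mean permuted
#' count of peaks scoring >= s divided by the observed count scoring
#' >= s, clipped to [0, 1] and made monotone non-increasing in s; each
#' peak is annotated with the FDR at its score.
#'
#' @param track probe-track data.frame used for the observed call.
#' @param peaks result of [call_peaks()] on `track`.
#' @param params the same [peak_params()] (its `seed` drives the
#'   shuffles).
#' @param global_ladder passed through to the permuted re-calls.
#' @return `peaks` with an `fdr` column; the per-rung FDR table is
#'   attached as attribute `fdr_table`.
#' @export
estimate_fdr <- function(track, peaks, params = peak_params(),
                         global_ladder = FALSE) {
  if (params$n_permutations < 1) stop("n_permutations must be >= 1")
  pct <- params$p_start - params$p_step * (seq_len(params$n_steps) - 1)
  obs_ge <- vapply(pct, function(s) sum(peaks$score >= s), numeric(1))
  perm_scores <- with_seed_if(params$seed, {
    lapply(seq_len(params$n_permutations), function(b) {
      sh <- track
      for (ch in unique(track$chrom)) {
        i <- track$chrom == ch
        sh$ratio[i] <- sample(track$ratio[i])
      }
      attr(sh, "spacing") <- attr(track, "spacing")
      call_peaks(sh, params, global_ladder)$score
    })
  })
  perm_ge <- vapply(pct, function(s) {
    mean(vapply(perm_scores, function(x) sum(x >= s), numeric(1)))
  }, numeric(1))
  raw <- ifelse(obs_ge > 0, pmin(pmax(perm_ge / obs_ge, 0), 1), NA_real_)
  ## monotone non-increasing in s: walking down the ladder, the FDR
  ## may only grow (cumulative max over the defined rungs above)
  mono <- raw
  run <- -Inf
  for (i in seq_along(mono)) {        # pct is descending in s
    if (!is.na(mono[i])) {
      run <- max(run, mono[i])
      mono[i] <- run
    }
  }
  peaks$fdr <- mono[match(peaks$score, pct)]
  attr(peaks, "fdr_table") <- data.frame(score = pct, obs_ge = obs_ge,
                                         perm_ge = perm_ge, fdr = mono)
  peaks
}

#' Filter peaks at a strict FDR threshold
#'
#' @param peaks FDR-annotated peak data.frame.
#' @param fdr_max strict threshold: peaks with `fdr < fdr_max` are kept.
#' @return filtered peaks, order preserved.
#' @export
filter_peaks <- function(peaks, fdr_max = 0.005) {
  if (!nrow(peaks)) return(peaks)
  if (!"fdr" %in% names(peaks)) stop("peaks have no fdr column")
  peaks[!is.na(peaks$fdr) & peaks$fdr < fdr_max, , drop = FALSE]
}
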