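#' Default pipeline configuration
#'
#' One nested list holding every stage's tunables with their standard
#' defaults (FDR 0.005, enrichment alpha 0.0005, fold-change threshold
#' 1.5, TSS windows 10 kb, DHS margin 1 kb, 30/40/30 expression
#' strata). `synth` keys mirror [synth_config()] fields.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    synth = list(n_chromosomes = 3, chrom_length = 2e6, gc_content = 0.41,
                 n_genes = 100, probe_spacing = 100, probe_length = 50,
                 n_true_peaks = 100, peak_length_mean = 692,
                 enrich_mu = 2.0, noise_sigma = 0.5,
                 motif_plant_rate = 0.55, dhs_overlap_rate = 0.1344,
                 de_up = 26, de_down = 47),
    peakcall = list(p_start = 90, p_step = 1, n_steps = 76,
                    min_probes = 4, min_probes_all_above = 2,
                    window = 500, fdr_max = 0.005, n_permutations = 20,
                    hypmax_k = 6),
    annotate = list(promoter_window = 10000, tes_window = 10000,
                    link_window = 10000, density_bin = 1e6),
    motif = list(width = 12, iterations = 1000, threshold_fraction = 0.8,
                 min_sequences = 5),
    tfbs = list(n_library = 20, n_controls = 10, threshold = 0.85,
                alpha = 0.0005,
                ctcf_pattern = "AG[GA][GT]GG[CAT][GAT][CG]"),
    profiles = list(window = 10000, bin = 200, fc_threshold = 1.5,
                    dhs_margin = 1000,
                    fractions = c(0.30, 0.40, 0.30)),
    downstream_peaks = "filtered"
  )
}

#' Read and validate a pipeline configuration (YAML)
#'
#' Unknown keys are rejected and missing keys reported by their full
#' dotted name; absent keys fall back to [default_config()] values only
#' at the stage level (a stage present in the file must be complete).
#'
#' @param path YAML file path.
#' @return validated nested list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  def <- default_config()
  bad <- setdiff(names(cfg), names(def))
  if (length(bad)) stop("unknown config section: ", paste(bad, collapse = ", "))
  for (sec in names(def)) {
    if (!sec %in% names(cfg)) {
      cfg[[sec]] <- def[[sec]]
      next
    }
    if (!is.list(def[[sec]])) next
    extra <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
    if (length(extra)) {
      stop("unknown config key: ", sec, ".", extra[1])
    }
    missing <- setdiff(names(def[[sec]]), names(cfg[[sec]]))
    if (length(missing)) {
      stop("config schema violation: missing key ", sec, ".", missing[1])
    }
  }
  cfg
}

#' Run the full pipeline: simulate, call peaks, annotate, motif,
#' enrichment, profiles
#'
#' Executes every stage in dependency order on a synthetic study,
#' writing each stage's outputs under `outdir` and a run manifest
#' (config snapshot, seed, per-stage output digests and status,
#' package version) as `manifest.json`. A single global seed is
#' expanded into fixed per-stage seeds so stages are independently
#' reproducible. Stages that need peak sequences run on the
#' FDR-filtered peaks by default (`downstream_peaks = "called"` uses
#' all scored peaks) and are recorded as skipped when fewer than
#' `motif$min_sequences` peaks remain.
#'
#' @param config nested list (see [default_config()]) or a YAML path.
#' @param outdir output directory.
#' @param seed integer master seed.
#' @return the manifest, invisibly; written to `outdir/manifest.json`.
#' @export
run_pipeline <- function(config = default_config(), outdir, seed = 1L) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  stages <- list()
  t_stage <- function(name, files, status = "ok") {
    files <- files[file.exists(files)]
    md5 <- tools::md5sum(files)
    stages[[name]] <<- list(
      status = status,
      outputs = as.list(setNames(unname(md5), basename(files)))
    )
  }
  p <- function(f) file.path(outdir, f)

  ## simulate
  sc <- do.call(synth_config, c(config$synth, list(seed = seed)))
  study <- simulate_study(sc)
  files <- write_study(study, outdir)
  t_stage("simulate", unname(files))

  ## callpeaks
  pc <- config$peakcall
  params <- peak_params(p_start = pc$p_start, p_step = pc$p_step,
                        n_steps = pc$n_steps, min_probes = pc$min_probes,
                        min_probes_all_above = pc$min_probes_all_above,
                        window = pc$window, fdr_max = pc$fdr_max,
                        n_permutations = pc$n_permutations,
                        hypmax_k = pc$hypmax_k,
                        seed = derive_seed(seed, "fdr"))
  peaks <- call_peaks(study$track, params)
  peaks <- estimate_fdr(study$track, peaks, params)
  peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  peaks$peak_id <- peaks$name
  filtered <- filter_peaks(peaks, pc$fdr_max)
  write_bed(peaks, p("peaks.bed"))
  write.table(peaks[, c("peak_id", "chrom", "start", "end", "score",
                        "n_probes", "mean_ratio", "fdr")],
              p("peaks.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(filtered, p("peaks_filtered.bed"))
  t_stage("callpeaks", p(c("peaks.bed", "peaks.tsv", "peaks_filtered.bed")))

  work <- if (identical(config$downstream_peaks, "called")) peaks else filtered

  ## annotate
  an <- config$annotate
  lens <- chrom_lengths(study$genome)
  if (nrow(work)) {
    cats <- assign_category(work, study$genes, lens,
                            an$promoter_window, an$tes_window)
    annotated <- cbind(work[, c("peak_id", "chrom", "start", "end",
                                "score", "fdr")],
                       category = as.character(cats))
    summary <- summarize_categories(work, study$genes, lens,
                                    an$promoter_window, an$tes_window)
    links <- map_peaks_to_genes(work, study$genes, an$link_window)
  } else {
    annotated <- data.frame()
    summary <- data.frame(category = FEATURE_CATEGORIES, count = 0,
                          percent = NA_real_)
    links <- list(links = data.frame(peak_id = character(0),
                                     gene_id = character(0),
                                     offset = numeric(0)),
                  n_peaks = 0, n_genes = 0)
  }
  dens <- density_track(work, lens, an$density_bin)
  write.table(annotated, p("annotated.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(summary, p("category_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(dens, p("density.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(links$links, p("peak_gene_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  t_stage("annotate", p(c("annotated.tsv", "category_summary.tsv",
                          "density.tsv", "peak_gene_links.tsv")))

  ## motif discovery
  mo <- config$motif
  if (nrow(work) >= mo$min_sequences) {
    seqs <- extract_sequences(study$genome, work)
    model <- gibbs_sample(seqs, width = mo$width,
                          iterations = mo$iterations,
                          seed = derive_seed(seed, "gibbs"))
    write_motif(model, p("motif.transfac"), p("motif_bits.tsv"))
    fr <- fraction_with_motif(model$pwm, seqs, mo$threshold_fraction)
    write.table(data.frame(peak_id = work$peak_id, has_motif = fr$flags),
                p("motif_report.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    t_stage("motif", p(c("motif.transfac", "motif_bits.tsv",
                         "motif_report.tsv")))
  } else {
    t_stage("motif", character(0), status = "skipped: too few peaks")
  }

  ## TFBS enrichment + consensus occupancy
  tf <- config$tfbs
  if (nrow(work) >= mo$min_sequences) {
    seqs <- extract_sequences(study$genome, work)
    lib <- random_pwm_library(tf$n_library,
                              seed = derive_seed(seed, "pwmlib"))
    ctrl <- sample_controls(work, study$genome, tf$n_controls,
                            seed = derive_seed(seed, "controls"))
    ctrl_seqs <- lapply(ctrl, extract_sequences, genome = study$genome)
    enr <- chi_square_enrichment(seqs, ctrl_seqs, lib, tf$threshold,
                                 tf$alpha)
    write.table(enr, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ctcf <- scan_consensus(seqs, consensus_pattern(tf$ctcf_pattern))
    write.table(data.frame(peak_id = work$peak_id, ctcf_hits = ctcf$counts),
                p("ctcf_scan.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    t_stage("enrich", p(c("enrichment.tsv", "ctcf_scan.tsv")))
  } else {
    t_stage("enrich", character(0), status = "skipped: too few peaks")
  }

  ## profiles, DE intersection, DHS co-occurrence
  pr <- config$profiles
  groups <- tertile_split(study$expression, pr$fractions)
  prof <- do.call(rbind, lapply(names(groups), function(gname) {
    tss_metaprofile(work, study$genes, groups[[gname]], pr$window,
                    pr$bin, group = gname)
  }))
  de <- intersect_de_genes(links$links, study$expression, pr$fc_threshold)
  co <- dhs_cooccurrence(work, study$dhs, pr$dhs_margin)
  write.table(prof, p("profiles.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene_id = c(de$up, de$down),
                         direction = rep(c("up", "down"),
                                         c(length(de$up), length(de$down)))),
              p("de_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(n_peaks = nrow(work),
                         dhs_fraction = co$fraction),
              p("dhs_cooccurrence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  t_stage("profiles", p(c("profiles.tsv", "de_genes.tsv",
                          "dhs_cooccurrence.tsv")))

  manifest <- list(
    package = "tilechip",
    version = as.character(utils::packageVersion("tilechip")),
    seed = seed,
    config = config,
    stages = stages
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
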