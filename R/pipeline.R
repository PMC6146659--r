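# End-to-end orchestration over a validated configuration: simulate ->
# quantify -> promoters -> enhancers -> induction -> TF association, with
# deterministic intermediate artifacts and a hashed manifest.

#' Build a pipeline configuration
#'
#' All thresholds default to the analysis' standard values and every one can
#' be overridden. Seeds for the individual stages are derived from the single
#' `seed` field.
#'
#' @param ... Named overrides of the default fields.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  config <- list(
    schema_version = 1L,
    design = default_design(),
    seed = 1L,
    # synthetic study size
    n_genes = 120L,
    chrom_length = 3e6,
    induced_fraction = 0.25,
    n_enhancers = 60L,
    # noise
    trend_coefficients = c(-0.5, -0.7, 0.08),
    count_depth = 1e6,
    wce_fraction = 0.1,
    # thresholds
    fdr_peaks = 0.01,
    fdr_tss = 0.001,
    merge_gap = 500L,
    z_sig = 4,
    z_time = 2,
    ratio_factor = 5,
    max_enhancer = 10000L,
    proximal = 2000L,
    assign_max = 150000L,
    ko_fold_factor = 5,
    # TF emulation
    tf_name = "STAT1",
    tf_onset = 2,
    tf_time_points = c(0, 0.5, 1, 2)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  config[names(overrides)] <- overrides
  validate_config(config)
  structure(config, class = "pipeline_config")
}

#' @keywords internal
#' @noRd
validate_config <- function(config) {
  check_design(config$design)
  thresholds <- c("fdr_peaks", "fdr_tss", "merge_gap", "z_sig", "z_time",
                  "ratio_factor", "max_enhancer", "proximal", "assign_max",
                  "ko_fold_factor")
  for (th in thresholds) {
    if (!is.numeric(config[[th]]) || length(config[[th]]) != 1L ||
        config[[th]] <= 0) {
      stop(sprintf("invalid config field '%s': must be a positive number", th))
    }
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    stop("invalid config field 'seed'")
  }
  if (config$n_genes < 2) stop("invalid config field 'n_genes': need >= 2")
  if (!config$tf_onset %in% config$tf_time_points) {
    stop("invalid config field 'tf_onset': must be one of tf_time_points")
  }
  invisible(config)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (schema", x$schema_version, ")\n")
  cat(sprintf("  design: %s h; seed %d\n", paste(x$design, collapse = ", "),
              as.integer(x$seed)))
  cat(sprintf("  %d genes on %g bp; %d candidate enhancers\n",
              x$n_genes, x$chrom_length, x$n_enhancers))
  cat(sprintf("  thresholds: peak FDR %g, TSS FDR %g, merge gap %d, Z >= %g / %g\n",
              x$fdr_peaks, x$fdr_tss, as.integer(x$merge_gap), x$z_sig,
              x$z_time))
  invisible(x)
}

# Place n distal regions in the intergenic space, at least `margin` bases
# away from gene bodies, deterministic for a seed.
#' @keywords internal
#' @noRd
place_distal_regions <- function(annotation, n, seed, margin = 2500L,
                                 size_range = c(1000L, 3000L)) {
  genes <- annotation$genes
  blocked <- GenomicRanges::reduce(as_granges(
    data.frame(chrom = genes$chrom,
               start = pmax(0L, genes$start - margin),
               end = pmin(annotation$chrom_length, genes$end + margin))
  ), ignore.strand = TRUE)
  free <- GenomicRanges::gaps(blocked)
  free <- free[GenomicRanges::strand(free) == "*"]
  free_df <- granges_to_df(free)
  free_df <- free_df[free_df$end - free_df$start > max(size_range) + 10L, ,
                     drop = FALSE]
  if (nrow(free_df) == 0L) stop("no intergenic space for distal regions")
  withr::with_seed(seed, {
    idx <- sample(seq_len(nrow(free_df)), n, replace = TRUE)
    len <- sample(size_range[1]:size_range[2], n, replace = TRUE)
    start <- vapply(seq_len(n), function(i) {
      lo <- free_df$start[idx[i]]
      hi <- free_df$end[idx[i]] - len[i]
      as.integer(lo + floor(runif(1) * (hi - lo)))
    }, integer(1))
    data.frame(chrom = free_df$chrom[idx], start = start,
               end = start + len, stringsAsFactors = FALSE)
  })
}

#' Run the pipeline end to end
#'
#' Executes the stages in dependency order on a synthetic study generated
#' from the configuration: simulate (annotation, ground truth, count series,
#' TSS reads, TF peaks) -> peak thresholding and merging -> quantification ->
#' promoter calling -> enhancer definition -> induction calling -> TF
#' association. Every artifact is written as a TSV/JSON file under `out_dir`
#' and recorded in a manifest with an MD5 content hash; rerunning with an
#' identical configuration reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest (named list with `config`, `artifacts`, `summary`),
#'   invisibly; also written to `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run_")) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- config$design
  seed <- as.integer(config$seed)
  noise <- noise_model(config$trend_coefficients, config$count_depth,
                       config$wce_fraction)
  artifacts <- character(0)
  save_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <<- c(artifacts, path)
    path
  }

  ## stage 1: simulate
  ann <- generate_annotation(config$n_genes, config$chrom_length, seed = seed)
  save_tsv(ann$genes, "genes.tsv")
  save_tsv(ann$exons, "exons.tsv")
  save_tsv(ann$cpg_islands, "cpg_islands.tsv")

  truth <- synthetic_truth(config$n_genes,
                           induced_fraction = config$induced_fraction,
                           design = design, seed = seed + 1L)
  truth$gene_id <- ann$genes$gene_id
  save_tsv(truth, "truth.tsv")

  prom_windows <- data.frame(
    chrom = ann$tss$chrom,
    start = pmax(0L, ann$tss$pos - 1000L),
    end = ann$tss$pos + 1000L,
    region_id = truth$region_id,
    stringsAsFactors = FALSE
  )
  counts <- simulate_count_series(truth, noise, design, seed = seed + 2L)

  # per-time-point peak calls: enrichment-ratio scores for the true calls
  # (IP vs WCE) and the control-swap calls (WCE vs IP)
  peak_sets <- lapply(seq_along(design), function(j) {
    true_peaks <- data.frame(
      prom_windows[, c("chrom", "start", "end")],
      score = (counts$ip[, j] + 1) / (counts$wce[, j] + 1)
    )
    control_peaks <- data.frame(
      prom_windows[, c("chrom", "start", "end")],
      score = (counts$wce[, j] + 1) / (counts$ip[, j] + 1)
    )
    list(true = true_peaks, control = control_peaks)
  })

  ip_reads <- scatter_reads(prom_windows, counts$ip, design,
                            chrom_length = config$chrom_length,
                            bg_reads = 0, seed = seed + 3L)
  wce_reads <- scatter_reads(prom_windows, counts$wce, design,
                             chrom_length = config$chrom_length,
                             bg_reads = 0, seed = seed + 4L)

  # TSS activity follows the same truth (sense strand)
  activity <- outer(truth$baseline_ppm / 20, rep(1, length(design)))
  onset <- ifelse(truth$is_induced, truth$true_induction_time, Inf)
  step <- outer(onset, design, FUN = function(o, t) t >= o)
  activity <- activity * (1 + (truth$effect_size - 1) * step)
  promoters_df <- data.frame(gene_id = ann$tss$gene_id, chrom = ann$tss$chrom,
                             tss = ann$tss$pos, strand = ann$tss$strand,
                             stringsAsFactors = FALSE)
  tss_reads <- simulate_tss_reads(promoters_df, activity, design,
                                  seed = seed + 5L)
  save_tsv(tss_reads, "tss_reads.tsv")

  ## stage 2: threshold, merge, quantify
  retained <- lapply(peak_sets, function(ps) {
    fdr_threshold_peaks(ps$true, ps$control, fdr = config$fdr_peaks)$peaks
  })
  regions <- merge_regions(do.call(rbind, retained), gap = config$merge_gap)
  save_tsv(regions, "regions.tsv")
  if (nrow(regions) == 0L) stop("no regions retained after FDR thresholding")
  signal <- quantify(regions, ip_reads, wce_reads, design,
                     feature = "H3K9K14ac",
                     ip_totals = config$count_depth,
                     wce_totals = config$count_depth)
  save_tsv(cbind(signal$regions, as.data.frame(signal$ppm)), "signal.tsv")

  ## stage 3: promoters
  tss_sum <- stats::aggregate(count ~ chrom + position + strand, data = tss_reads,
                              FUN = sum)
  evidence <- data.frame(regions[, c("chrom", "start", "end")],
                         value = rowSums(signal$ppm))
  promoters <- call_promoters(tss_sum, ann, fdr = config$fdr_tss,
                              seed = seed + 6L, pol2 = evidence)
  save_tsv(promoters, "promoters.tsv")

  ## stage 4: enhancers
  distal <- place_distal_regions(ann, config$n_enhancers, seed = seed + 7L)
  me1_regions <- rbind(distal, prom_windows[seq_len(min(10L, nrow(prom_windows))),
                                            c("chrom", "start", "end")])
  me1_ppm <- c(withr::with_seed(seed + 8L,
                                runif(nrow(distal), 20, 60)),
               rep(5, nrow(me1_regions) - nrow(distal)))
  me3_ppm <- c(rep(1, nrow(distal)),
               rep(50, nrow(me1_regions) - nrow(distal)))
  enhancers <- define_enhancers(me1_regions, promoters, ann$exons,
                                me1_ppm, me3_ppm,
                                proximal = config$proximal,
                                max_size = config$max_enhancer,
                                ratio_factor = config$ratio_factor)
  enhancers$assigned_promoter <- assign_to_promoter(
    enhancers, promoters, max_distance = config$assign_max
  )
  save_tsv(enhancers, "enhancers.tsv")

  ## stage 5: induction calling
  fit <- fit_dispersion_trend(signal)
  calls <- call_induction(signal, fit, z_sig = config$z_sig,
                          z_time = config$z_time)
  save_tsv(as.data.frame(calls), "induction_calls.tsv")
  fit_json <- file.path(out_dir, "dispersion_fit.json")
  jsonlite::write_json(
    list(feature = fit$feature, coefficients = as.list(fit$coefficients),
         support = fit$support),
    fit_json, auto_unbox = TRUE, digits = NA
  )
  artifacts <- c(artifacts, fit_json)

  ## stage 6: TF association
  induced_regions <- regions$region_id[
    match(truth$region_id[truth$is_induced], prom_windows$region_id,
          nomatch = 0L)]
  # the TF targets the truly induced promoter regions with a fixed onset
  target_idx <- which(truth$is_induced)
  binding_truth <- data.frame(
    tf = config$tf_name,
    region_id = prom_windows$region_id,
    chrom = prom_windows$chrom,
    start = prom_windows$start,
    end = prom_windows$end,
    onset_time = ifelse(truth$is_induced, config$tf_onset, NA_real_),
    stringsAsFactors = FALSE
  )
  tf <- simulate_tf_peaks(binding_truth, time_points = config$tf_time_points,
                          seed = seed + 9L)
  save_tsv(tf$peaks, "tf_peaks.tsv")
  bound <- bound_regions(regions, tf$peaks, tf$threshold,
                         time_points = config$tf_time_points)
  events <- new_binding_events(bound)
  newly_bound <- regions$region_id[!is.na(events)]
  increased <- calls$region_id[calls$significant]
  ov <- overlap_fisher(newly_bound, increased, regions$region_id)
  curves_bound <- timing_fraction_curves(calls, newly_bound, design)
  curves_unbound <- timing_fraction_curves(
    calls, setdiff(regions$region_id, newly_bound), design)
  tf_summary <- data.frame(
    time = design,
    fraction_bound = curves_bound$fraction,
    fraction_unbound = curves_unbound$fraction
  )
  save_tsv(tf_summary, "tf_timing_curves.tsv")

  manifest <- list(
    config = unclass(config),
    artifacts = lapply(artifacts, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }),
    summary = list(
      n_regions = nrow(regions),
      n_promoters = nrow(promoters),
      n_enhancers = nrow(enhancers),
      n_significant = sum(calls$significant),
      tf_overlap_minus_log10_p = ov$minus_log10_p
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
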