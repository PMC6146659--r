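# Signal quantification: peak FDR thresholding, region merging, WCE
# correction, RPKM, quantile normalization and ppm conversion.

#' Threshold peak calls at a fixed empirical FDR
#'
#' Peak callers run in both orientations give true calls (IP vs control) and
#' negative-control calls (control vs IP). The empirical false discovery rate
#' at a score threshold `theta` is the ratio of control calls to true calls
#' with score `>= theta`; the retained threshold is the smallest true-call
#' score at which this ratio is at or below `fdr`. Computed per time point
#' and per feature by the caller.
#'
#' @param true_peaks `data.frame` of true peak calls with a `score` column.
#' @param control_peaks `data.frame` of negative-control calls with `score`.
#' @param fdr Target false discovery rate.
#' @return List with `peaks` (the retained rows of `true_peaks`) and
#'   `threshold` (the retained score threshold; `Inf` and zero retained peaks
#'   if no threshold meets the bound; the minimum score when there are no
#'   control peaks). An empty `true_peaks` yields an empty result.
#' @export
fdr_threshold_peaks <- function(true_peaks, control_peaks, fdr = 0.01) {
  stopifnot(is.numeric(fdr), fdr >= 0)
  if (nrow(true_peaks) == 0L) {
    return(list(peaks = true_peaks, threshold = Inf))
  }
  if (any(!is.finite(true_peaks$score))) stop("peak scores must be finite")
  cand <- sort(unique(true_peaks$score))
  n_true <- vapply(cand, function(th) sum(true_peaks$score >= th), numeric(1))
  n_ctrl <- vapply(cand, function(th) sum(control_peaks$score >= th),
                   numeric(1))
  ok <- (n_ctrl / n_true) <= fdr
  if (!any(ok)) {
    return(list(peaks = true_peaks[0, , drop = FALSE], threshold = Inf))
  }
  threshold <- min(cand[ok])
  list(peaks = true_peaks[true_peaks$score >= threshold, , drop = FALSE],
       threshold = threshold)
}

#' Merge peak regions across time points
#'
#' Collects retained peaks over all time points and merges, first, peaks that
#' overlap and, second, peaks separated by less than `gap` bases. Two
#' half-open intervals `[a, b)` and `[c, d)` with `c >= b` are merged iff
#' `c - b < gap`.
#'
#' @param peaks `data.frame` with `chrom`, `start`, `end` (0-based,
#'   half-open); rows may come from any number of time points and in any
#'   order.
#' @param gap Merge distance in bases (default 500).
#' @return `data.frame` of disjoint merged regions (`chrom`, `start`, `end`,
#'   `region_id`), sorted by position; any two output regions on the same
#'   chromosome are separated by at least `gap` bases.
#' @export
merge_regions <- function(peaks, gap = 500L) {
  check_scalar_positive(gap, "gap")
  if (nrow(peaks) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), region_id = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- GenomicRanges::reduce(as_granges(peaks), min.gapwidth = gap,
                              ignore.strand = TRUE)
  out <- granges_to_df(gr)
  out$strand <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Whole-cell-extract read-count correction
#'
#' Subtracts from the IP read count of a region the expected number of
#' non-specific reads, estimated from the WCE control count rescaled by the
#' depth ratio of the two libraries, flooring at zero. The result estimates
#' the IP reads that would remain if no background reads were present.
#'
#' @param ip_count,wce_count Read counts in the region (vectorized).
#' @param ip_total,wce_total Total mapped reads of the IP and WCE libraries.
#' @return Corrected count(s), `max(0, ip - wce * ip_total / wce_total)`.
#' @export
correct_counts <- function(ip_count, wce_count, ip_total, wce_total) {
  check_scalar_positive(ip_total, "ip_total")
  check_scalar_positive(wce_total, "wce_total")
  corrected <- ip_count - wce_count * ip_total / wce_total
  corrected[corrected < 0] <- 0
  corrected
}

#' Reads per kilobase per million mapped reads
#'
#' @param count (Corrected) read count(s).
#' @param region_length Region length(s) in bases.
#' @param total_reads Total mapped reads of the library.
#' @return RPKM value(s): `count * 1e9 / (region_length * total_reads)`.
#' @export
rpkm <- function(count, region_length, total_reads) {
  if (any(region_length <= 0)) stop("region_length must be positive")
  check_scalar_positive(total_reads, "total_reads")
  count * 1e9 / (region_length * total_reads)
}

#' Quantile normalization across time points
#'
#' Forces every column (time point) of a region-by-time matrix onto the same
#' distribution: the row-wise mean of the sorted columns. Ties receive the
#' mean of the reference values at their rank positions. Performed per
#' feature across its own time points only, under the assumption that the
#' genome-wide signal distribution does not change substantially over the
#' course.
#'
#' @param m Numeric matrix, regions x time points (>= 2 columns).
#' @return Matrix of the same shape; idempotent up to numerical tolerance.
#' @export
quantile_normalize <- function(m) {
  stopifnot(is.matrix(m), ncol(m) >= 2L, nrow(m) >= 1L)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Convert normalized RPKM to reads per million (ppm)
#'
#' Undoes the per-kilobase rescaling of RPKM so that values are on the reads
#' per million scale for each region: `ppm = rpkm * region_length / 1000`.
#'
#' @param normalized_rpkm RPKM value(s).
#' @param region_length Region length(s) in bases.
#' @return ppm value(s).
#' @export
to_ppm <- function(normalized_rpkm, region_length) {
  if (any(region_length <= 0)) stop("region_length must be positive")
  normalized_rpkm * region_length / 1000
}

# Count reads (position tables) falling in half-open regions.
#' @keywords internal
#' @noRd
count_in_regions <- function(regions, reads) {
  counts <- numeric(nrow(regions))
  if (nrow(reads) == 0L) return(counts)
  gr_regions <- as_granges(regions)
  gr_reads <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$position + 1L, width = 1L)
  )
  hits <- GenomicRanges::findOverlaps(gr_reads, gr_regions,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(counts)
  agg <- tapply(reads$count[S4Vectors::queryHits(hits)],
                S4Vectors::subjectHits(hits), sum)
  counts[as.integer(names(agg))] <- as.numeric(agg)
  counts
}

#' Quantify a feature over merged regions across a time course
#'
#' Composes the full quantification chain for one feature: count IP and WCE
#' reads per region and time point, correct the IP counts for background
#' ([correct_counts()]), convert to RPKM, quantile-normalize across the time
#' points and convert to ppm.
#'
#' @param regions Merged regions from [merge_regions()] (`chrom`, `start`,
#'   `end`, `region_id`).
#' @param ip_reads,wce_reads Named lists (one element per design label, see
#'   [default_design()]) of read-position tables with columns `chrom`,
#'   `position`, `count`.
#' @param design Time-course design in hours.
#' @param feature Feature name attached to the result.
#' @param ip_totals,wce_totals Total mapped reads of the IP and WCE
#'   libraries, a single number or one per time point; defaults to the
#'   column sums of the read tables (appropriate when the tables cover the
#'   whole genome).
#' @return Object of class `region_signal`: list with `regions`, `ppm`
#'   (matrix regions x time points), `design` and `feature`.
#' @export
quantify <- function(regions, ip_reads, wce_reads, design = default_design(),
                     feature = "feature", ip_totals = NULL,
                     wce_totals = NULL) {
  check_design(design)
  labels <- design_labels(design)
  missing_ip <- setdiff(labels, names(ip_reads))
  missing_wce <- setdiff(labels, names(wce_reads))
  if (length(missing_ip) > 0 || length(missing_wce) > 0) {
    stop(sprintf("missing time point table(s): %s",
                 paste(unique(c(missing_ip, missing_wce)), collapse = ", ")))
  }
  lens <- regions$end - regions$start
  if (!is.null(ip_totals)) ip_totals <- rep_len(ip_totals, length(design))
  if (!is.null(wce_totals)) wce_totals <- rep_len(wce_totals, length(design))
  rpkm_mat <- matrix(0, nrow(regions), length(design),
                     dimnames = list(regions$region_id, labels))
  for (j in seq_along(labels)) {
    ip <- ip_reads[[labels[j]]]
    wce <- wce_reads[[labels[j]]]
    ip_total <- if (is.null(ip_totals)) sum(ip$count) else ip_totals[j]
    wce_total <- if (is.null(wce_totals)) sum(wce$count) else wce_totals[j]
    ip_counts <- count_in_regions(regions, ip)
    wce_counts <- count_in_regions(regions, wce)
    corrected <- correct_counts(ip_counts, wce_counts, ip_total, wce_total)
    rpkm_mat[, j] <- rpkm(corrected, lens, ip_total)
  }
  norm <- quantile_normalize(rpkm_mat)
  ppm <- to_ppm(norm, lens)
  structure(
    list(regions = regions, ppm = ppm, design = design, feature = feature),
    class = "region_signal"
  )
}

#' Construct a region_signal from a ppm matrix
#'
#' Light-weight constructor for workflows where ppm values are already
#' available (e.g. synthetic counts converted directly).
#'
#' @param regions Region table (`chrom`, `start`, `end`, `region_id`), or
#'   `NULL` to derive placeholder ids from the matrix rownames.
#' @param ppm Matrix regions x time points.
#' @param design Time-course design.
#' @param feature Feature name.
#' @return Object of class `region_signal`.
#' @export
region_signal <- function(ppm, design = default_design(), regions = NULL,
                          feature = "feature") {
  check_design(design)
  stopifnot(is.matrix(ppm), ncol(ppm) == length(design), all(ppm >= 0))
  if (is.null(rownames(ppm))) {
    rownames(ppm) <- sprintf("region_%05d", seq_len(nrow(ppm)))
  }
  colnames(ppm) <- design_labels(design)
  if (is.null(regions)) {
    regions <- data.frame(region_id = rownames(ppm), stringsAsFactors = FALSE)
  }
  structure(list(regions = regions, ppm = ppm, design = design,
                 feature = feature),
            class = "region_signal")
}

#' @export
print.region_signal <- function(x, ...) {
  cat(sprintf("region_signal: %d regions x %d time points, feature '%s'\n",
              nrow(x$ppm), ncol(x$ppm), x$feature))
  cat(sprintf("  design (h): %s\n", paste(x$design, collapse = ", ")))
  cat(sprintf("  ppm range: [%.3g, %.3g]\n", min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' Write a region_signal to a TSV file
#'
#' One row per region with `region_id`, coordinates when available, the
#' feature, and one ppm column per time point.
#'
#' @param x A `region_signal`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_region_signal <- function(x, path) {
  stopifnot(inherits(x, "region_signal"))
  df <- x$regions
  df$feature <- x$feature
  df <- cbind(df, as.data.frame(x$ppm))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
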