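# TF binding association: bound/new-binding flags from peak-score tables,
# overlap enrichment by Fisher's exact test, binding-site metaprofiles, and
# induction-timing curves.

#' Flag regions bound by a TF at each time point
#'
#' A region is bound at a time point if any peak of that time point with a
#' score at or above the threshold overlaps the region's analysis window
#' (half-open overlap; a single shared base counts). Analysis windows are
#' TSS +/- 1 kb for promoters and the full region (or center +/- 1 kb for
#' regions under 2 kb) for enhancers; pass the windows directly.
#'
#' @param windows `data.frame` with `chrom`, `window_start`, `window_end`
#'   (or `start`/`end`).
#' @param peaks Peak table (`chrom`, `start`, `end`, `score`, `time`).
#' @param threshold Score threshold for significant binding.
#' @param time_points Time points to evaluate; defaults to the sorted unique
#'   times in `peaks`.
#' @return Logical matrix, regions x time points (columns named by time).
#' @export
bound_regions <- function(windows, peaks, threshold,
                          time_points = sort(unique(peaks$time))) {
  w <- data.frame(
    chrom = windows$chrom,
    start = if ("window_start" %in% names(windows)) windows$window_start
            else windows$start,
    end = if ("window_end" %in% names(windows)) windows$window_end
          else windows$end,
    stringsAsFactors = FALSE
  )
  gr_w <- as_granges(w)
  out <- matrix(FALSE, nrow(w), length(time_points),
                dimnames = list(NULL, as.character(time_points)))
  sig <- peaks[peaks$score >= threshold, , drop = FALSE]
  for (j in seq_along(time_points)) {
    pj <- sig[sig$time == time_points[j], , drop = FALSE]
    if (nrow(pj) == 0L) next
    out[, j] <- IRanges::overlapsAny(gr_w, as_granges(pj),
                                     ignore.strand = TRUE)
  }
  out
}

#' Extract new-binding events from a bound-flag series
#'
#' A new-binding event at time `t` requires significant binding at `t` and no
#' significant binding at any earlier available time point. Regions bound at
#' their earliest available time point are pre-bound and yield no event. TFs
#' missing time points are handled naturally: "earlier" means earlier among
#' the columns supplied.
#'
#' @param bound Logical matrix regions x available time points, columns
#'   ordered and named by time.
#' @return Numeric vector of event times (NA where there is no event), one
#'   per region.
#' @export
new_binding_events <- function(bound) {
  stopifnot(is.matrix(bound), is.logical(bound))
  times <- as.numeric(colnames(bound))
  apply(bound, 1, function(b) {
    first <- which(b)[1]
    if (is.na(first) || first == 1L) return(NA_real_)
    if (any(b[seq_len(first - 1L)])) return(NA_real_)  # defensive; first T
    times[first]
  })
}

#' Overlap enrichment between two region sets (Fisher's exact test)
#'
#' Builds the 2x2 contingency table of membership in `set_a` versus `set_b`
#' over a universe of regions and evaluates it with the two-sided Fisher
#' exact test.
#'
#' @param set_a,set_b Character vectors of region ids (subsets of
#'   `universe`).
#' @param universe Character vector of all region ids.
#' @return List of class `overlap_test` with `table` (2x2 counts: rows =
#'   in/out of `set_a`, columns = in/out of `set_b`), `odds_ratio`,
#'   `p_value` and `minus_log10_p`.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("universe must be non-empty")
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("set_a and set_b must be subsets of universe")
  }
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- matrix(
    c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("in_a", "out_a"), c("in_b", "out_b"))
  )
  ft <- fisher.test(tab, alternative = "two.sided")
  structure(
    list(table = tab, odds_ratio = unname(ft$estimate),
         p_value = ft$p.value, minus_log10_p = -log10(ft$p.value)),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Overlap enrichment (two-sided Fisher's exact test)\n")
  print(x$table)
  cat(sprintf("  odds ratio %.3g, p = %.3g (-log10 p = %.2f)\n",
              x$odds_ratio, x$p_value, x$minus_log10_p))
  invisible(x)
}

#' Overlap-enrichment matrix for heatmaps
#'
#' Convenience wrapper computing `-log10 p` of [overlap_fisher()] for every
#' pair of a list of binding sets (rows) and a list of increase sets
#' (columns).
#'
#' @param binding_sets Named list of region-id vectors (e.g. newly bound per
#'   TF).
#' @param increase_sets Named list of region-id vectors (e.g. induced per
#'   feature).
#' @param universe All region ids.
#' @return Numeric matrix of `-log10 p` values.
#' @export
overlap_matrix <- function(binding_sets, increase_sets, universe) {
  out <- matrix(NA_real_, length(binding_sets), length(increase_sets),
                dimnames = list(names(binding_sets), names(increase_sets)))
  for (i in seq_along(binding_sets)) {
    for (j in seq_along(increase_sets)) {
      out[i, j] <- overlap_fisher(binding_sets[[i]], increase_sets[[j]],
                                  universe)$minus_log10_p
    }
  }
  out
}

#' Binding-site-anchored signal metaprofile
#'
#' Averages a per-base signal track around anchor points (peak midpoints) in
#' 100-bp bins, per time point. The track is given as disjoint regions with
#' per-time-point ppm values interpreted as a per-base level constant over
#' each region. Bins are half-open `[k*bin, (k+1)*bin)` relative to the
#' anchor; the bin value is the mean per-base signal over the bin, averaged
#' across anchors.
#'
#' @param track_regions `data.frame` (`chrom`, `start`, `end`) of the signal
#'   regions.
#' @param values Matrix (regions x time points) of per-base signal levels.
#' @param anchors `data.frame` with `chrom` and `pos` (anchor base, e.g.
#'   peak midpoint).
#' @param bin Bin width in bases (default 100).
#' @param halfwidth Profile half-width in bases (default 2 kb).
#' @return List with `profile` (matrix bins x time points; rownames are bin
#'   start offsets) and `window_sum` (per-time-point sum of the bin means
#'   over the full window).
#' @export
binding_site_profile <- function(track_regions, values, anchors,
                                 bin = 100L, halfwidth = 2000L) {
  if (nrow(anchors) == 0L) stop("no anchor sites supplied")
  stopifnot(nrow(track_regions) == nrow(values))
  n_bins <- 2L * (halfwidth %/% bin)
  offsets <- seq(-halfwidth, halfwidth - bin, by = bin)
  nt <- ncol(values)
  acc <- matrix(0, n_bins, nt)
  for (i in seq_len(nrow(anchors))) {
    b_start <- anchors$pos[i] + offsets
    b_end <- b_start + bin
    sel <- which(track_regions$chrom == anchors$chrom[i] &
                   track_regions$start < max(b_end) &
                   track_regions$end > min(b_start))
    if (length(sel) == 0L) next
    for (r in sel) {
      ov <- pmax(0, pmin(b_end, track_regions$end[r]) -
                   pmax(b_start, track_regions$start[r]))
      nz <- which(ov > 0)
      if (length(nz) > 0L) {
        acc[nz, ] <- acc[nz, ] + (ov[nz] / bin) %o% values[r, ]
      }
    }
  }
  profile <- acc / nrow(anchors)
  rownames(profile) <- offsets
  colnames(profile) <- colnames(values)
  list(profile = profile, window_sum = colSums(profile))
}

#' Fraction of regions induced at each time point
#'
#' Given induction calls, returns per time point the fraction of a region set
#' whose induction time equals that time point. Typically computed for a
#' TF-bound set and its complement to compare timing.
#'
#' @param calls An `induction_calls` data.frame (see [call_induction()]).
#' @param region_ids Region ids of the set to evaluate; defaults to all.
#' @param design Time-course design in hours.
#' @return `data.frame` with `time` and `fraction`; fractions over all time
#'   points sum to (number significant in set) / (set size).
#' @export
timing_fraction_curves <- function(calls, region_ids = calls$region_id,
                                   design = default_design()) {
  sel <- calls$region_id %in% region_ids
  n <- sum(sel)
  if (n == 0L) stop("empty region set")
  frac <- vapply(design, function(t) {
    sum(sel & calls$significant & !is.na(calls$induction_time) &
          calls$induction_time == t) / n
  }, numeric(1))
  data.frame(time = design, fraction = frac)
}

#' Compare significant increases between wild type and knockout
#'
#' Splits two call sets over the same region universe into wild-type-only,
#' shared and knockout-only significant regions and, optionally, reports the
#' fraction of each group bound by each TF.
#'
#' @param calls_wt,calls_ko `induction_calls` over the same universe.
#' @param bound_sets Optional named list (per TF) of bound region-id vectors.
#' @return List with `counts` (named vector `wt_only`, `shared`, `ko_only`),
#'   the three id vectors, and (when `bound_sets` is given) `bound_fraction`,
#'   a matrix TF x group.
#' @export
wt_ko_increase_comparison <- function(calls_wt, calls_ko,
                                      bound_sets = NULL) {
  stopifnot(identical(sort(calls_wt$region_id), sort(calls_ko$region_id)))
  sig_wt <- calls_wt$region_id[calls_wt$significant]
  sig_ko <- calls_ko$region_id[calls_ko$significant]
  groups <- list(
    wt_only = setdiff(sig_wt, sig_ko),
    shared = intersect(sig_wt, sig_ko),
    ko_only = setdiff(sig_ko, sig_wt)
  )
  res <- list(
    counts = vapply(groups, length, integer(1)),
    wt_only = groups$wt_only, shared = groups$shared,
    ko_only = groups$ko_only
  )
  if (!is.null(bound_sets)) {
    bf <- matrix(NA_real_, length(bound_sets), 3L,
                 dimnames = list(names(bound_sets), names(groups)))
    for (i in seq_along(bound_sets)) {
      for (j in seq_along(groups)) {
        g <- groups[[j]]
        bf[i, j] <- if (length(g) == 0L) NA_real_ else
          mean(g %in% bound_sets[[i]])
      }
    }
    res$bound_fraction <- bf
  }
  res
}
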