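# Enhancer definition from H3K4me1-significant regions and assignment to the
# nearest promoter.

#' Define enhancers from H3K4me1-significant regions
#'
#' Starting from merged regions with significant H3K4me1 in at least one time
#' point, removes (1) regions any part of which lies closer than `proximal`
#' bases to a promoter window or an exon, (2) regions larger than `max_size`
#' bases, and (3) regions whose time-summed H3K4me1 ppm is less than
#' `ratio_factor` times their time-summed H3K4me3 ppm (promoter-like
#' regions). Distances are minimal base separations under half-open
#' coordinates (overlap = distance 0).
#'
#' @param me1_regions `data.frame` (`chrom`, `start`, `end`, optionally
#'   `region_id`) of H3K4me1-significant merged regions.
#' @param promoters Promoter table with `chrom`, `window_start`,
#'   `window_end`.
#' @param exons Exon table (`chrom`, `start`, `end`).
#' @param me1_ppm,me3_ppm H3K4me1 and H3K4me3 signal for the rows of
#'   `me1_regions`: either vectors of time-summed ppm or matrices
#'   (regions x time points), which are summed over time.
#' @param proximal Minimum distance to promoter windows and exons (default
#'   2 kb).
#' @param max_size Maximum enhancer size (default 10 kb).
#' @param ratio_factor Required H3K4me1 : H3K4me3 ratio (default 5).
#' @return `data.frame` of enhancers: coordinates, `enhancer_id`, `center`
#'   (midpoint base) and the analysis window `window_start`/`window_end`
#'   (the full interval, or center +/- 1 kb for enhancers smaller than 2 kb).
#' @export
define_enhancers <- function(me1_regions, promoters, exons, me1_ppm, me3_ppm,
                             proximal = 2000L, max_size = 10000L,
                             ratio_factor = 5) {
  if (is.matrix(me1_ppm)) me1_ppm <- rowSums(me1_ppm)
  if (is.matrix(me3_ppm)) me3_ppm <- rowSums(me3_ppm)
  stopifnot(length(me1_ppm) == nrow(me1_regions),
            length(me3_ppm) == nrow(me1_regions))
  if (nrow(me1_regions) == 0L) {
    return(cbind(me1_regions,
                 data.frame(center = integer(0), window_start = integer(0),
                            window_end = integer(0))))
  }
  gr <- as_granges(me1_regions)

  prox_windows <- data.frame(chrom = promoters$chrom,
                             start = promoters$window_start,
                             end = promoters$window_end)
  obstacles <- rbind(prox_windows, exons[, c("chrom", "start", "end")])
  near <- rep(FALSE, nrow(me1_regions))
  if (nrow(obstacles) > 0L) {
    dtn <- GenomicRanges::distanceToNearest(gr, as_granges(obstacles),
                                            ignore.strand = TRUE)
    near[S4Vectors::queryHits(dtn)] <-
      S4Vectors::mcols(dtn)$distance < proximal
  }
  too_big <- (me1_regions$end - me1_regions$start) > max_size
  promoter_like <- me1_ppm < ratio_factor * me3_ppm

  keep <- !near & !too_big & !promoter_like
  out <- me1_regions[keep, , drop = FALSE]
  if (!"region_id" %in% names(out)) {
    out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  }
  out$enhancer_id <- sprintf("enh_%05d", seq_len(nrow(out)))
  out$center <- (out$start + out$end) %/% 2L
  small <- (out$end - out$start) < 2000L
  out$window_start <- ifelse(small, out$center - 1000L, out$start)
  out$window_end <- ifelse(small, out$center + 1000L, out$end)
  rownames(out) <- NULL
  out
}

#' Assign enhancers to their nearest promoter
#'
#' Each enhancer is assigned to the promoter whose TSS is closest to the
#' enhancer center (center-to-center distance); no assignment is made when
#' the nearest promoter is `max_distance` bases or farther away. Exact ties
#' go to the upstream promoter (smaller coordinate).
#'
#' @param enhancers Enhancer table from [define_enhancers()] (needs `chrom`
#'   and `center`).
#' @param promoters Promoter table (`gene_id`, `chrom`, `tss`).
#' @param max_distance Maximum center-to-center distance (default 150 kb).
#' @return Character vector of assigned `gene_id`s (NA where unassigned),
#'   one per enhancer.
#' @export
assign_to_promoter <- function(enhancers, promoters,
                               max_distance = 150000L) {
  if (nrow(enhancers) == 0L) return(character(0))
  vapply(seq_len(nrow(enhancers)), function(i) {
    p <- promoters[promoters$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(p) == 0L) return(NA_character_)
    dist <- abs(p$tss - enhancers$center[i])
    best <- min(dist)
    if (best >= max_distance) return(NA_character_)
    cand <- p[dist == best, , drop = FALSE]
    cand$gene_id[which.min(cand$tss)]
  }, character(1))
}
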