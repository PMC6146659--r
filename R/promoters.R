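# TSS-seq promoter calling: multi-scale scanning windows against a
# randomized null, candidate filtering, representative-TSS selection, and
# annotation-based supplementation.

TSS_WINDOW_SIZES <- c(1L, 10L, 50L, 100L, 500L, 1000L)
TSS_WINDOW_STEPS <- c(1L, 1L, 5L, 10L, 50L, 100L)

#' Scan strand-specific 5'-end counts with multi-scale windows
#'
#' Counts TSS-seq 5'-end reads in windows of size 1, 10, 50, 100, 500 and
#' 1000 bases, advanced in steps of 1, 1, 5, 10, 50 and 100 bases, separately
#' per strand. Every step-offset window containing at least one read is
#' reported with its contained read count; windows are half-open
#' `[k*step, k*step + size)`.
#'
#' @param reads `data.frame` with columns `chrom`, `position` (0-based),
#'   `strand`, `count`.
#' @param sizes,steps Window sizes and matching step sizes.
#' @return `data.frame` with `chrom`, `start`, `end`, `strand`,
#'   `window_size`, `read_count`.
#' @export
scan_windows <- function(reads, sizes = TSS_WINDOW_SIZES,
                         steps = TSS_WINDOW_STEPS) {
  stopifnot(length(sizes) == length(steps))
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      window_size = integer(0), read_count = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  out <- vector("list", length(sizes))
  for (sc in seq_along(sizes)) {
    w <- sizes[sc]
    s <- steps[sc]
    # window k covers [k*s, k*s + w); read at p is in windows
    # k in [floor((p - w)/s) + 1, floor(p/s)], clipped at 0
    k_hi <- reads$position %/% s
    k_lo <- pmax(0L, (reads$position - w) %/% s + 1L)
    nrep <- k_hi - k_lo + 1L
    dt <- data.table::data.table(
      chrom = rep(reads$chrom, nrep),
      strand = rep(reads$strand, nrep),
      count = rep(reads$count, nrep),
      k = sequence(nrep, from = k_lo, by = 1L)
    )
    agg <- dt[, list(read_count = sum(count)),
              by = c("chrom", "strand", "k")]
    agg[, `:=`(start = k * s, end = k * s + w, window_size = w)]
    data.table::setorder(agg, chrom, strand, start)
    out[[sc]] <- as.data.frame(
      agg[, c("chrom", "start", "end", "strand", "window_size", "read_count"),
          with = FALSE]
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build a randomized null for the scanning-window caller
#'
#' Places a number of read alignments exactly matching the real data at
#' uniformly random positions (random strand) on the genome and scans them
#' with identical parameters. At desk scale the toy genome is fully mappable
#' by construction, so no mappability masking is applied.
#'
#' @param reads Real read table (`chrom`, `position`, `strand`, `count`).
#' @param chrom_length Genome (chromosome) length in bases.
#' @param seed Integer seed.
#' @param chrom Chromosome name for the null reads.
#' @param sizes,steps Scanning parameters, as in [scan_windows()].
#' @return List with `reads` (the randomized read table; total count equals
#'   the real total) and `hits` (its [scan_windows()] result).
#' @export
build_null <- function(reads, chrom_length, seed = 1L, chrom = "chrS",
                       sizes = TSS_WINDOW_SIZES, steps = TSS_WINDOW_STEPS) {
  check_scalar_positive(chrom_length, "chrom_length")
  n <- sum(reads$count)
  null_reads <- withr::with_seed(seed, {
    pos <- sample.int(chrom_length, n, replace = TRUE) - 1L
    strand <- sample(c("+", "-"), n, replace = TRUE)
    dt <- data.table::data.table(chrom = chrom, position = pos,
                                 strand = strand)
    agg <- dt[, list(count = .N), by = c("chrom", "position", "strand")]
    data.table::setorder(agg, chrom, strand, position)
    as.data.frame(agg)
  })
  list(reads = null_reads, hits = scan_windows(null_reads, sizes, steps))
}

#' Call significant TSS windows against the null
#'
#' For each window size, the count threshold is the smallest count `c` with
#' `(# null windows >= c) / (# real windows >= c) <= fdr`. Each significant
#' window is assigned the empirical FDR at its own count. Overlapping
#' significant windows (per strand, across all sizes) are resolved by keeping
#' the window with the lowest FDR, breaking ties by higher read count and
#' then smaller window size.
#'
#' @param real,null [scan_windows()] results produced with identical
#'   parameters.
#' @param fdr Target FDR (default 0.001).
#' @return `data.frame` of retained windows with columns as in
#'   [scan_windows()] plus `fdr_value`.
#' @export
call_significant_windows <- function(real, null, fdr = 0.001) {
  stopifnot(is.numeric(fdr), fdr >= 0)
  kept <- vector("list", 0L)
  for (w in sort(unique(real$window_size))) {
    rw <- real[real$window_size == w, , drop = FALSE]
    nw_counts <- null$read_count[null$window_size == w]
    cand <- sort(unique(rw$read_count))
    n_real <- vapply(cand, function(cc) sum(rw$read_count >= cc), numeric(1))
    n_null <- vapply(cand, function(cc) sum(nw_counts >= cc), numeric(1))
    efdr <- n_null / n_real
    ok <- efdr <= fdr
    if (!any(ok)) next
    c_star <- min(cand[ok])
    sig <- rw[rw$read_count >= c_star, , drop = FALSE]
    sig$fdr_value <- efdr[match(sig$read_count, cand)]
    kept[[length(kept) + 1L]] <- sig
  }
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      window_size = integer(0), read_count = integer(0),
                      fdr_value = numeric(0), stringsAsFactors = FALSE)
  if (length(kept) == 0L) return(empty)
  hits <- do.call(rbind, kept)

  # resolve overlaps across window sizes, per strand
  gr <- as_granges(hits)
  clusters <- GenomicRanges::reduce(gr, ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, clusters, ignore.strand = FALSE)
  cl <- rep(NA_integer_, nrow(hits))
  cl[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  ord <- order(cl, hits$fdr_value, -hits$read_count, hits$window_size,
               hits$start)
  hits <- hits[ord, , drop = FALSE]
  res <- hits[!duplicated(cl[ord]), , drop = FALSE]
  res <- res[order(res$chrom, res$strand, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter TSS candidates by annotation
#'
#' Removes candidates located within 3' UTRs and candidates more than
#' `max_upstream` bases upstream of every gene, where "upstream" is measured
#' on the candidate's strand against gene starts of the same strand. A
#' candidate that overlaps a gene or lies within/downstream of one is kept
#' (subject to the 3'-UTR rule).
#'
#' @param candidates `data.frame` with `chrom`, `start`, `end`, `strand`.
#' @param annotation A [generate_annotation()] bundle, or any list with
#'   `genes` and `utr3` tables.
#' @param max_upstream Maximum upstream distance in bases (default 50 kb).
#' @return Filtered `candidates`.
#' @export
filter_tss <- function(candidates, annotation, max_upstream = 50000L) {
  if (nrow(candidates) == 0L) return(candidates)
  gr <- as_granges(candidates)

  # 3' UTR overlap (strand-agnostic: any candidate inside a UTR is noise)
  in_utr <- rep(FALSE, nrow(candidates))
  if (nrow(annotation$utr3) > 0L) {
    utr <- as_granges(annotation$utr3)
    in_utr <- IRanges::overlapsAny(gr, utr, ignore.strand = TRUE)
  }

  genes <- annotation$genes
  too_far <- vapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    g <- genes[genes$strand == cand$strand & genes$chrom == cand$chrom, ,
               drop = FALSE]
    if (nrow(g) == 0L) return(TRUE)
    gap <- if (cand$strand == "+") g$start - cand$end else
      cand$start - g$end
    # gap <= 0 means the candidate overlaps or lies downstream of the gene
    # start: not "upstream of" that gene
    min(pmax(gap, 0)) > max_upstream
  }, logical(1))

  out <- candidates[!in_utr & !too_far, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sum of evidence values overlapping [pos - flank, pos + flank).
#' @keywords internal
#' @noRd
evidence_at <- function(evidence, chrom, pos, flank) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(0)
  sel <- evidence$chrom == chrom &
    evidence$start < pos + flank & evidence$end > pos - flank
  sum(evidence$value[sel])
}

#' Select one representative promoter per gene
#'
#' Within each candidate region the representative TSS is the single base
#' with the maximal TSS-seq read count (ties resolved to the 5'-most base on
#' the gene strand). Candidates without any Pol2 or H3K4me3 evidence within
#' +/- `flank` of the representative base are discarded as TSS-seq-only
#' noise. Each surviving candidate is attached to the nearest same-strand
#' gene TSS; among a gene's candidates the one with the maximal TSS-seq count
#' wins, ties resolved to the candidate closest to the annotated gene start.
#'
#' @param candidates Significant TSS regions (`chrom`, `start`, `end`,
#'   `strand`).
#' @param tss_reads Read table (`chrom`, `position`, `strand`, `count`),
#'   summed over time points.
#' @param gene_tss Annotation TSS table (`gene_id`, `chrom`, `pos`,
#'   `strand`).
#' @param pol2,h3k4me3 Optional evidence tables (`chrom`, `start`, `end`,
#'   `value` = time-summed ppm); pass `NULL` for both to skip the evidence
#'   filter.
#' @param flank Evidence and promoter window half-width (default 1 kb).
#' @return `data.frame` of promoters: `gene_id`, `chrom`, `tss`, `strand`,
#'   `source = "tss_seq"`, `window_start`, `window_end`, `tss_count`.
#' @export
select_representative <- function(candidates, tss_reads, gene_tss,
                                  pol2 = NULL, h3k4me3 = NULL,
                                  flank = 1000L) {
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      tss = integer(0), strand = character(0),
                      source = character(0), window_start = integer(0),
                      window_end = integer(0), tss_count = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(candidates) == 0L) return(empty)
  use_evidence <- !is.null(pol2) || !is.null(h3k4me3)

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    rr <- tss_reads[tss_reads$chrom == cand$chrom &
                      tss_reads$strand == cand$strand &
                      tss_reads$position >= cand$start &
                      tss_reads$position < cand$end, , drop = FALSE]
    if (nrow(rr) == 0L) return(NULL)
    per_base <- tapply(rr$count, rr$position, sum)
    best <- as.integer(names(per_base)[per_base == max(per_base)])
    rep_base <- if (cand$strand == "+") min(best) else max(best)

    if (use_evidence) {
      ev <- evidence_at(pol2, cand$chrom, rep_base, flank) +
        evidence_at(h3k4me3, cand$chrom, rep_base, flank)
      if (ev <= 0) return(NULL)
    }

    g <- gene_tss[gene_tss$chrom == cand$chrom &
                    gene_tss$strand == cand$strand, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    dist <- abs(g$pos - rep_base)
    gi <- which.min(dist)
    data.frame(
      gene_id = g$gene_id[gi], chrom = cand$chrom, tss = rep_base,
      strand = cand$strand, source = "tss_seq",
      window_start = rep_base - flank, window_end = rep_base + flank,
      tss_count = sum(rr$count), gene_dist = dist[gi],
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(empty)

  # one promoter per gene: maximal TSS-seq count, ties to the candidate
  # closest to the annotated gene start
  res <- res[order(res$gene_id, -res$tss_count, res$gene_dist, res$tss), ,
             drop = FALSE]
  res <- res[!duplicated(res$gene_id), , drop = FALSE]
  res$gene_dist <- NULL
  rownames(res) <- NULL
  res
}

#' Supplement promoters with annotation-based TSSs
#'
#' Every gene lacking a TSS-seq-based promoter receives its annotation TSS,
#' provided the +/- `flank` window around it does not overlap an
#' already-accepted promoter window. Annotation TSSs are processed in sorted
#' gene_id order; each accepted window also blocks later additions, so the
#' final set is mutually non-overlapping among supplemented entries.
#'
#' @param promoters TSS-seq-based promoters from [select_representative()].
#' @param gene_tss Annotation TSS table (`gene_id`, `chrom`, `pos`,
#'   `strand`).
#' @param flank Promoter window half-width (default 1 kb).
#' @return Combined promoter `data.frame`; `source` distinguishes
#'   `"tss_seq"` from `"annotation"` entries. At most one promoter per gene.
#' @export
supplement_refseq <- function(promoters, gene_tss, flank = 1000L) {
  missing_genes <- setdiff(gene_tss$gene_id, promoters$gene_id)
  missing_genes <- sort(missing_genes)
  windows <- promoters[, c("chrom", "window_start", "window_end")]
  out <- promoters
  for (g in missing_genes) {
    row <- gene_tss[gene_tss$gene_id == g, , drop = FALSE]
    ws <- row$pos - flank
    we <- row$pos + flank
    overlaps <- any(windows$chrom == row$chrom &
                      windows$window_start < we & windows$window_end > ws)
    if (overlaps) next
    add <- data.frame(
      gene_id = g, chrom = row$chrom, tss = row$pos, strand = row$strand,
      source = "annotation", window_start = ws, window_end = we,
      tss_count = 0, stringsAsFactors = FALSE
    )
    out <- rbind(out, add)
    windows <- rbind(windows,
                     data.frame(chrom = row$chrom, window_start = ws,
                                window_end = we, stringsAsFactors = FALSE))
  }
  out <- out[order(out$chrom, out$tss), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag CpG-island-associated promoters
#'
#' A promoter is CpG-associated if any CpG island overlaps the
#' `[tss - flank, tss + flank)` window around its TSS.
#'
#' @param promoters Promoter table with `chrom` and `tss` columns.
#' @param cpg_islands Island intervals (`chrom`, `start`, `end`).
#' @param flank Window half-width (default 1 kb).
#' @return Logical vector, one flag per promoter.
#' @export
classify_cpg <- function(promoters, cpg_islands, flank = 1000L) {
  if (nrow(promoters) == 0L) return(logical(0))
  if (nrow(cpg_islands) == 0L) return(rep(FALSE, nrow(promoters)))
  win <- data.frame(chrom = promoters$chrom,
                    start = pmax(0L, promoters$tss - flank),
                    end = promoters$tss + flank)
  IRanges::overlapsAny(as_granges(win), as_granges(cpg_islands),
                       ignore.strand = TRUE)
}

#' Call promoters from TSS-seq reads end to end
#'
#' Convenience wrapper composing [scan_windows()], [build_null()],
#' [call_significant_windows()], [filter_tss()], [select_representative()],
#' [supplement_refseq()] and [classify_cpg()].
#'
#' @param tss_reads Read table (`chrom`, `position`, `strand`, `count`),
#'   summed over the time course.
#' @param annotation Annotation bundle (see [generate_annotation()]).
#' @param fdr Scanning-window FDR (default 0.001).
#' @param seed Seed for the randomized null.
#' @param pol2,h3k4me3 Optional evidence tables for
#'   [select_representative()].
#' @param flank Promoter window half-width.
#' @return Promoter `data.frame` with a `cpg` flag column.
#' @export
call_promoters <- function(tss_reads, annotation, fdr = 0.001, seed = 1L,
                           pol2 = NULL, h3k4me3 = NULL, flank = 1000L) {
  real <- scan_windows(tss_reads)
  null <- build_null(tss_reads, annotation$chrom_length, seed = seed,
                     chrom = annotation$chrom)
  sig <- call_significant_windows(real, null$hits, fdr = fdr)
  sig <- filter_tss(sig, annotation)
  prom <- select_representative(sig, tss_reads, annotation$tss,
                                pol2 = pol2, h3k4me3 = h3k4me3, flank = flank)
  prom <- supplement_refseq(prom, annotation$tss, flank = flank)
  prom$cpg <- classify_cpg(prom, annotation$cpg_islands, flank = flank)
  prom
}
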