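# Internal helpers: coordinate conversion and input checks.
#
# All user-facing tables use 0-based, half-open coordinates (BED convention):
# a region [start, end) covers bases start .. end-1. GenomicRanges objects
# (1-based, closed) are used internally for interval arithmetic only.

#' @keywords internal
#' @noRd
as_granges <- function(df, keep = FALSE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if (keep) {
    extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
    for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
  }
  gr
}

#' @keywords internal
#' @noRd
granges_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' @keywords internal
#' @noRd
check_design <- function(design) {
  if (length(design) < 2L) stop("design must contain at least two time points")
  if (design[1] != 0) stop("design must start at 0 h")
  if (any(diff(design) <= 0)) stop("design must be strictly increasing")
  invisible(design)
}

#' @keywords internal
#' @noRd
check_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name))
  }
  invisible(x)
}

# Column names used for the per-time-point ppm matrix.
#' @keywords internal
#' @noRd
design_labels <- function(design) paste0("t", as.character(design))
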