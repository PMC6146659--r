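# The replicate-free induction model.
#
# For each region x and feature f, with ppm values over the design:
#   m = median over time points, s = population SD, d = (s/m)^2.
# A quadratic least-squares trend of log10 d on log10 m over all promoter and
# enhancer regions gives the expected dispersion at any signal level; the
# trend-implied SD, s_fitted = m * sqrt(d_fitted), scales deviations from the
# 0 h baseline into Z-scores:
#   Z_t = (ppm_t - ppm_0h) / s_fitted.
# A region is significantly induced if Z >= 4 at some time point and its
# signal passes a low-signal filter; the induction time is the first time
# point with Z >= 2.

#' Per-region summary statistics over the time course
#'
#' Computes, for each row of a ppm matrix, the median `m`, the population
#' standard deviation `s` (dividing by the number of time points), and the
#' dispersion `d = (s/m)^2`. Regions with `m = 0` get `d = NA` and are
#' excluded from trend fitting.
#'
#' @param ppm Numeric matrix, regions x time points, or a `region_signal`.
#' @return `data.frame` with columns `region_id`, `m`, `s`, `d`.
#' @export
region_stats <- function(ppm) {
  if (inherits(ppm, "region_signal")) ppm <- ppm$ppm
  stopifnot(is.matrix(ppm), ncol(ppm) >= 2L)
  n <- ncol(ppm)
  m <- apply(ppm, 1, median)
  mu <- rowMeans(ppm)
  s <- sqrt(rowSums((ppm - mu)^2) / n)
  d <- ifelse(m > 0, (s / m)^2, NA_real_)
  data.frame(
    region_id = if (is.null(rownames(ppm)))
      sprintf("region_%05d", seq_len(nrow(ppm))) else rownames(ppm),
    m = m, s = s, d = d, stringsAsFactors = FALSE
  )
}

#' Fit the mean-dispersion trend for one feature
#'
#' Least-squares fit of `log10(d) = a0 + a1*log10(m) + a2*log10(m)^2` over
#' all usable regions (those with `m > 0` and `d > 0`). The trend is fit per
#' feature on the union of promoter and enhancer regions of one dataset, so a
#' short-course dataset (e.g. a two-time-point knockout comparison) gets its
#' own fit.
#'
#' @param signal A `region_signal`, a ppm matrix (regions x time points), or
#'   a stats `data.frame` from [region_stats()]. Several signals (e.g.
#'   promoter and enhancer ppm matrices for the same feature) can be combined
#'   by passing a list; their stats are pooled before fitting.
#' @param feature Feature name; taken from a `region_signal` when available.
#' @return Object of class `dispersion_trend` with elements `coefficients`
#'   (`a0`, `a1`, `a2`), `support` (number of regions used), `stats` (pooled
#'   per-region statistics), `model` (the underlying `lm` fit) and `feature`.
#' @seealso [z_scores()], [call_induction()]
#' @export
fit_dispersion_trend <- function(signal, feature = NULL) {
  if (inherits(signal, "region_signal")) {
    if (is.null(feature)) feature <- signal$feature
    stats_df <- region_stats(signal$ppm)
  } else if (is.matrix(signal)) {
    stats_df <- region_stats(signal)
  } else if (is.data.frame(signal) && all(c("m", "d") %in% names(signal))) {
    stats_df <- signal
  } else if (is.list(signal)) {
    parts <- lapply(signal, function(s) {
      if (inherits(s, "region_signal")) region_stats(s$ppm) else region_stats(s)
    })
    stats_df <- do.call(rbind, parts)
  } else {
    stop("'signal' must be a region_signal, ppm matrix, stats data.frame, or list thereof")
  }
  if (is.null(feature)) feature <- "feature"
  usable <- !is.na(stats_df$d) & stats_df$d > 0 & stats_df$m > 0
  if (sum(usable) < 3L) {
    stop(sprintf("need at least 3 usable regions to fit the trend, got %d",
                 sum(usable)))
  }
  u <- log10(stats_df$m[usable])
  v <- log10(stats_df$d[usable])
  fit <- lm(v ~ u + I(u^2))
  coefs <- unname(coef(fit))
  structure(
    list(
      coefficients = setNames(coefs, c("a0", "a1", "a2")),
      support = sum(usable),
      stats = stats_df,
      usable = usable,
      model = fit,
      feature = feature
    ),
    class = "dispersion_trend"
  )
}

#' @export
print.dispersion_trend <- function(x, ...) {
  cat(sprintf("Mean-dispersion trend for feature '%s'\n", x$feature))
  cat(sprintf(
    "  log10(d) = %.4f %+.4f*log10(m) %+.4f*log10(m)^2\n",
    x$coefficients[1], x$coefficients[2], x$coefficients[3]
  ))
  cat(sprintf("  fitted on %d regions (of %d)\n", x$support,
              nrow(x$stats)))
  invisible(x)
}

#' @export
coef.dispersion_trend <- function(object, ...) object$coefficients

#' @export
summary.dispersion_trend <- function(object, ...) {
  res <- list(
    feature = object$feature,
    coefficients = object$coefficients,
    support = object$support,
    n_regions = nrow(object$stats),
    r_squared = summary(object$model)$r.squared,
    residual_sd = summary(object$model)$sigma
  )
  class(res) <- "summary.dispersion_trend"
  res
}

#' @export
print.summary.dispersion_trend <- function(x, ...) {
  cat(sprintf("Mean-dispersion trend: feature '%s'\n", x$feature))
  cat(sprintf("  coefficients: a0 = %.4f, a1 = %.4f, a2 = %.4f\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  support: %d of %d regions; R^2 = %.3f; residual SD = %.3f (log10 units)\n",
              x$support, x$n_regions, x$r_squared, x$residual_sd))
  invisible(x)
}

#' Predict dispersion and trend-implied SD at given median levels
#'
#' @param object A `dispersion_trend` fit.
#' @param newdata Numeric vector of median ppm values; defaults to the
#'   medians of the fitted regions.
#' @param ... Unused.
#' @return `data.frame` with `m`, `dispersion` (fitted `d`) and `sd_fitted`
#'   (`m * sqrt(d)`).
#' @export
predict.dispersion_trend <- function(object, newdata = NULL, ...) {
  m <- if (is.null(newdata)) object$stats$m[object$usable] else newdata
  if (any(m <= 0)) stop("median values must be positive")
  d <- trend_dispersion(m, object$coefficients)
  data.frame(m = m, dispersion = d, sd_fitted = m * sqrt(d))
}

#' @export
residuals.dispersion_trend <- function(object, ...) {
  residuals(object$model)
}

#' @export
fitted.dispersion_trend <- function(object, ...) {
  fitted(object$model)
}

#' Plot the mean-dispersion trend
#'
#' Scatter of per-region log10 dispersion against log10 median ppm with the
#' fitted quadratic overlaid.
#'
#' @param x A `dispersion_trend`.
#' @param ... Passed to `plot()`.
#' @export
plot.dispersion_trend <- function(x, ...) {
  u <- log10(x$stats$m[x$usable])
  v <- log10(x$stats$d[x$usable])
  plot(u, v, pch = 16, cex = 0.4, col = "grey50",
       xlab = "log10 median ppm", ylab = "log10 dispersion",
       main = sprintf("Mean-dispersion trend (%s)", x$feature), ...)
  uu <- seq(min(u), max(u), length.out = 200)
  lines(uu, x$coefficients[1] + x$coefficients[2] * uu +
          x$coefficients[3] * uu^2, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Simulate stable series from a fitted trend
#'
#' Draws stable (non-induced) ppm series whose per-region SD follows the
#' fitted trend, as a Gaussian approximation truncated at zero. Useful for
#' parametric-bootstrap checks of the caller's false-positive rate.
#'
#' @param object A `dispersion_trend`.
#' @param nsim Number of series per median level.
#' @param seed Integer seed.
#' @param median_ppm Median levels to simulate at; defaults to the fitted
#'   regions' medians.
#' @param n_time Number of time points per series.
#' @param ... Unused.
#' @return Matrix with `nsim * length(median_ppm)` rows and `n_time` columns.
#' @export
simulate.dispersion_trend <- function(object, nsim = 1, seed = 1L,
                                      median_ppm = NULL, n_time = 10L, ...) {
  m <- if (is.null(median_ppm)) object$stats$m[object$usable] else median_ppm
  pred <- predict(object, m)
  withr::with_seed(seed, {
    mm <- rep(pred$m, each = nsim)
    ss <- rep(pred$sd_fitted, each = nsim)
    mat <- matrix(pmax(0, stats::rnorm(length(mm) * n_time, mean = mm,
                                       sd = ss)),
                  nrow = length(mm), ncol = n_time)
    mat
  })
}

#' Baseline-anchored Z-scores from a fitted trend
#'
#' For each region, `Z_t = (ppm_t - ppm_0h) / s_fitted`, with
#' `s_fitted = m * sqrt(10^(a0 + a1*log10(m) + a2*log10(m)^2))`. `Z` at 0 h
#' is exactly 0. Regions with `m = 0` (so `s_fitted` undefined) get `NA`
#' rows and are non-significant by definition.
#'
#' @param signal A `region_signal` or ppm matrix (regions x time points; the
#'   first column is the 0 h baseline).
#' @param fit A `dispersion_trend` for the same feature.
#' @return Matrix of Z-scores with the shape of the input ppm matrix.
#' @export
z_scores <- function(signal, fit) {
  ppm <- if (inherits(signal, "region_signal")) signal$ppm else signal
  stopifnot(is.matrix(ppm), inherits(fit, "dispersion_trend"))
  m <- apply(ppm, 1, median)
  s_fitted <- rep(NA_real_, nrow(ppm))
  ok <- m > 0
  s_fitted[ok] <- m[ok] * sqrt(trend_dispersion(m[ok], fit$coefficients))
  s_fitted[!is.na(s_fitted) & s_fitted <= 0] <- NA_real_
  z <- (ppm - ppm[, 1]) / s_fitted
  dimnames(z) <- dimnames(ppm)
  z
}

#' Call significant inductions and induction times
#'
#' A region is significantly induced if its Z-score reaches `z_sig` (default
#' 4) at some time point and its ppm reaches the low-signal cut at some time
#' point. The low-signal cut defaults to the 25th percentile of the non-zero
#' ppm values of the feature, computed over all regions and time points. For
#' significant regions the induction time is the first time point with
#' `Z >= z_time` (default 2).
#'
#' @param signal A `region_signal` or ppm matrix.
#' @param fit A `dispersion_trend` for the feature.
#' @param design Time-course design; taken from `signal` when it is a
#'   `region_signal`.
#' @param z_sig Z threshold for significance.
#' @param z_time Z threshold defining the induction time.
#' @param low_signal_cut Low-signal filter; `NULL` for the feature-wise 25th
#'   percentile of non-zero ppm.
#' @return `data.frame` of class `induction_calls` with columns `region_id`,
#'   `feature`, `significant`, `induction_time` (NA unless significant),
#'   `max_z` and `basal` (ppm at 0 h). The Z matrix is attached as attribute
#'   `"z"`, the cut as `"low_signal_cut"`.
#' @export
call_induction <- function(signal, fit, design = NULL, z_sig = 4,
                           z_time = 2, low_signal_cut = NULL) {
  ppm <- if (inherits(signal, "region_signal")) signal$ppm else signal
  if (is.null(design)) {
    design <- if (inherits(signal, "region_signal")) signal$design else
      stop("'design' required when 'signal' is a plain matrix")
  }
  check_design(design)
  stopifnot(ncol(ppm) == length(design))
  if (is.null(rownames(ppm))) {
    rownames(ppm) <- sprintf("region_%05d", seq_len(nrow(ppm)))
  }
  z <- z_scores(ppm, fit)
  if (is.null(low_signal_cut)) {
    nz <- ppm[ppm > 0]
    low_signal_cut <- if (length(nz) > 0) unname(quantile(nz, 0.25)) else 0
  }
  max_z <- apply(z, 1, function(r) if (all(is.na(r))) NA_real_ else
    max(r, na.rm = TRUE))
  passes_signal <- apply(ppm >= low_signal_cut, 1, any)
  significant <- !is.na(max_z) & max_z >= z_sig & passes_signal
  induction_time <- rep(NA_real_, nrow(ppm))
  for (i in which(significant)) {
    idx <- which(z[i, ] >= z_time)[1]
    induction_time[i] <- design[idx]
  }
  out <- data.frame(
    region_id = rownames(ppm),
    feature = fit$feature,
    significant = significant,
    induction_time = induction_time,
    max_z = max_z,
    basal = ppm[, 1],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "z") <- z
  attr(out, "low_signal_cut") <- low_signal_cut
  class(out) <- c("induction_calls", class(out))
  out
}

#' @export
print.induction_calls <- function(x, ...) {
  cat(sprintf(
    "induction_calls: %d regions, feature '%s'; %d significant (%.2f%%)\n",
    nrow(x), x$feature[1], sum(x$significant),
    100 * mean(x$significant)
  ))
  if (any(x$significant)) {
    tt <- table(x$induction_time[x$significant])
    cat("  induction times (h): ",
        paste(sprintf("%s h: %d", names(tt), tt), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Call stimulus-induced promoters from TSS-seq signal
#'
#' Promoters are induced if their sense-strand TSS-seq Z-score reaches
#' `z_sig` at some time point and their TSS-seq ppm reaches `min_ppm`
#' (default 1) at some time point; the transcription induction time is the
#' first time point with `Z >= z_time`. Only reads aligned in the sense
#' orientation of the associated gene should be quantified into `signal`.
#'
#' @param signal `region_signal` (or ppm matrix) of sense-strand TSS-seq ppm
#'   per promoter.
#' @param fit `dispersion_trend` fitted to the TSS-seq feature.
#' @param design Time-course design (taken from `signal` when available).
#' @param z_sig,z_time Z thresholds (defaults 4 and 2).
#' @param min_ppm Minimum ppm at some time point (default 1).
#' @return An `induction_calls` data.frame (see [call_induction()]).
#' @export
call_lps_induced_promoters <- function(signal, fit, design = NULL,
                                       z_sig = 4, z_time = 2, min_ppm = 1) {
  call_induction(signal, fit, design = design, z_sig = z_sig,
                 z_time = z_time, low_signal_cut = min_ppm)
}

#' Identify promoters with unchanged activity
#'
#' A promoter is unchanged if `|Z| < 1` at every time point.
#'
#' @param z Z-score matrix (e.g. `attr(calls, "z")` or [z_scores()]).
#' @return Logical vector, one element per region (NA-safe: regions with
#'   undefined Z are not unchanged).
#' @export
call_unchanged_promoters <- function(z) {
  stopifnot(is.matrix(z))
  res <- apply(z, 1, function(r) all(!is.na(r)) && all(abs(r) < 1))
  unname(res)
}

#' Classify basal (0 h) levels into absent/low/high
#'
#' Regions with zero basal signal are "absent". The remaining regions are
#' sorted by basal level (ties broken by region id for determinism) and split
#' into two classes of equal size; with an odd count the extra region goes to
#' the low class.
#'
#' @param basal Numeric vector of 0 h ppm values.
#' @param region_id Region identifiers (used for tie-breaking); defaults to
#'   the names of `basal` or the index.
#' @return Factor with levels `absent`, `low`, `high`, in input order.
#' @export
basal_level_classes <- function(basal, region_id = NULL) {
  if (is.null(region_id)) {
    region_id <- if (!is.null(names(basal))) names(basal) else
      as.character(seq_along(basal))
  }
  stopifnot(length(basal) == length(region_id), all(basal >= 0))
  cls <- rep(NA_character_, length(basal))
  cls[basal == 0] <- "absent"
  idx <- which(basal > 0)
  if (length(idx) > 0) {
    ord <- idx[order(basal[idx], region_id[idx])]
    n_low <- ceiling(length(ord) / 2)
    cls[ord[seq_len(n_low)]] <- "low"
    if (n_low < length(ord)) {
      cls[ord[(n_low + 1):length(ord)]] <- "high"
    }
  }
  factor(cls, levels = c("absent", "low", "high"))
}

#' Knockout dependence of gene induction
#'
#' A gene's fold-induction in a genotype is the maximum over time of
#' `(x_t + epsilon) / (x_0 + epsilon)` on quantile-normalized RPKM series;
#' the gene is dependent on the knocked-out pathway if the wild-type
#' fold-induction is more than `factor` (default 5) times the knockout
#' fold-induction.
#'
#' @param wt_series,ko_series Matrices (genes x time points) of normalized
#'   RPKM; first column is 0 h.
#' @param epsilon Pseudocount in RPKM units (default 0.1).
#' @param factor Dependence factor (default 5).
#' @return `data.frame` with `fold_wt`, `fold_ko` and logical `dependent`.
#' @export
ko_dependence <- function(wt_series, ko_series, epsilon = 0.1, factor = 5) {
  stopifnot(is.matrix(wt_series), is.matrix(ko_series),
            nrow(wt_series) == nrow(ko_series))
  fold <- function(m) {
    apply((m + epsilon) / (m[, 1] + epsilon), 1, max)
  }
  fold_wt <- fold(wt_series)
  fold_ko <- fold(ko_series)
  data.frame(
    gene = if (is.null(rownames(wt_series)))
      sprintf("gene_%05d", seq_len(nrow(wt_series))) else rownames(wt_series),
    fold_wt = fold_wt,
    fold_ko = fold_ko,
    dependent = fold_wt > factor * fold_ko,
    stringsAsFactors = FALSE
  )
}
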