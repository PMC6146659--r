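# Synthetic data with known ground truth.
#
# Everything downstream (quantification, promoter/enhancer definition,
# induction calling, TF association) is tested against data produced here, so
# the generator is first-class, deterministic code: every function takes an
# explicit seed and restores the caller's RNG state.

#' Default time-course design
#'
#' The ten-time-point stimulation design used throughout the package:
#' 0, 0.5, 1, 2, 3, 4, 6, 8, 16 and 24 hours. Arbitrary designs (e.g. the
#' 0/1/2/4 h replicate course or a 0/4 h knockout comparison) are accepted by
#' every function that takes a `design` argument.
#'
#' @return Numeric vector of time points in hours.
#' @export
default_design <- function() c(0, 0.5, 1, 2, 3, 4, 6, 8, 16, 24)

#' Noise model for synthetic count series
#'
#' Describes the count noise of the generator: the quadratic trend of log10
#' dispersion (squared coefficient of variation) as a function of log10
#' median signal, the expected sequencing depth, and the expected fraction of
#' non-specific (background) reads.
#'
#' Count noise is Poisson-lognormal: Poisson sampling around a per-region
#' biological level with log-normal extra-Poisson scatter. Marginally this is
#' negative-binomial-like, with mean and variance matched to the trend. By
#' default samples are independent across time points (`bio_rho = 0`);
#' setting `bio_rho > 0` makes the extra-Poisson component a stationary
#' log-scale AR(1) process, for experiments where adjacent samples of a
#' replicate-free course share biological noise.
#'
#' Defaults give dispersions comfortably above the Poisson floor over
#' baselines of 10-3000 ppm, with coefficients of variation falling from
#' about 0.5 at 10 ppm to about 0.08 at 3000 ppm, flattening at high signal
#' as is typical for ChIP-seq region counts.
#'
#' @param trend_coefficients Numeric of length 3, `(a0, a1, a2)` such that
#'   `log10(dispersion) = a0 + a1*log10(m) + a2*log10(m)^2` where `m` is the
#'   median ppm of a region over the time course.
#' @param count_depth Expected number of mapped reads per sample.
#' @param wce_fraction Expected background fraction: the mean non-specific
#'   signal at a region is `wce_fraction` times its baseline ppm.
#' @param bio_rho Lag-1 autocorrelation (per design step) of the log-scale
#'   biological noise component.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(trend_coefficients = c(1, -1.8, 0.25),
                        count_depth = 1e6,
                        wce_fraction = 0.1,
                        bio_rho = 0) {
  if (length(trend_coefficients) != 3L || !is.numeric(trend_coefficients)) {
    stop("'trend_coefficients' must be a numeric vector of length 3")
  }
  check_scalar_positive(count_depth, "count_depth")
  if (!is.numeric(wce_fraction) || wce_fraction < 0 || wce_fraction >= 1) {
    stop("'wce_fraction' must satisfy 0 <= wce_fraction < 1")
  }
  if (!is.numeric(bio_rho) || bio_rho < 0 || bio_rho >= 1) {
    stop("'bio_rho' must satisfy 0 <= bio_rho < 1")
  }
  structure(
    list(
      trend_coefficients = as.numeric(trend_coefficients),
      count_depth = count_depth,
      wce_fraction = wce_fraction,
      bio_rho = bio_rho
    ),
    class = "noise_model"
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("Synthetic count noise model\n")
  cat(sprintf(
    "  log10 dispersion trend: %.3f %+.3f*u %+.3f*u^2  (u = log10 median ppm)\n",
    x$trend_coefficients[1], x$trend_coefficients[2], x$trend_coefficients[3]
  ))
  cat(sprintf(
    "  depth: %g reads/sample, background fraction: %g, noise AR(1) rho: %g\n",
    x$count_depth, x$wce_fraction, x$bio_rho))
  invisible(x)
}

# Evaluate the trend: dispersion (cv^2) at median ppm m.
#' @keywords internal
#' @noRd
trend_dispersion <- function(m, coefficients) {
  u <- log10(m)
  10^(coefficients[1] + coefficients[2] * u + coefficients[3] * u^2)
}

# Median of the marginal count distribution (negative-binomial-like with
# mean mu and variance var); used so the measured dispersion, which divides
# by the squared sample median, stays centred on the trend for skewed counts.
#' @keywords internal
#' @noRd
nb_median <- function(mu, var) {
  med <- mu
  pos <- mu > 0
  size <- ifelse(var > mu, mu^2 / (var - mu), Inf)
  over <- pos & is.finite(size)
  med[over] <- stats::qnbinom(0.5, mu = mu[over], size = size[over])
  med[pos & !is.finite(size)] <- stats::qpois(0.5, mu[pos & !is.finite(size)])
  med
}

# Calibration of the estimator bias for independent samples: the population
# variance of n points is biased by (n-1)/n and taking logs adds the
# chi-square Jensen term digamma((n-1)/2) - log((n-1)/2); the excess-kurtosis
# term 6*d adds the non-normal part, E[log s^2] - log sigma^2 ~ -kappa/(2n).
# The generated variance is inflated accordingly so the *measured* dispersion
# is centred on the trend.
#' @keywords internal
#' @noRd
variance_calibration <- function(n) {
  1 / ((n - 1) / n * exp(digamma((n - 1) / 2) - log((n - 1) / 2)))
}

# Calibration of the log-scale biological noise variance for autocorrelated
# (bio_rho > 0) noise so that the *measured* dispersion of a stable region
# (population variance of the n-point series divided by the squared sample
# median) is approximately centred on the trend. The series covariance of
# Poisson-lognormal counts with AR(1) log-mixing is
# Sigma = diag(mu) + mu^2*(exp(s2b*rho^|i-j|) - 1); the expected log of the
# quadratic form s^2 = x'Cx is evaluated to second order (Jensen term from
# Var(s^2) = 2 tr((C Sigma)^2)), and s2b is solved by bisection. Regions at
# the Poisson floor get s2b = 0.
#' @keywords internal
#' @noRd
expected_log_s2 <- function(s2b, m, Rm, Cm) {
  n <- nrow(Rm)
  Sig <- diag(rep(m, n)) + m^2 * expm1(s2b * Rm)
  CS <- Cm %*% Sig
  E <- sum(diag(CS))
  V <- 2 * sum(CS * t(CS))
  log(E) - V / (2 * E^2)
}

#' @keywords internal
#' @noRd
calibrate_bio_var <- function(m_count, d_target, rho, n) {
  Rm <- rho^abs(outer(seq_len(n), seq_len(n), "-"))
  Cm <- (diag(n) - 1 / n) / n
  solve_one <- function(m, d) {
    if (m <= 0 || d <= 0) return(0)
    med <- m
    s2b <- 0
    for (pass in 1:2) {
      target <- log(d) + 2 * log(max(med, 0.5))
      if (expected_log_s2(0, m, Rm, Cm) >= target) {
        s2b <- 0
      } else {
        hi <- log1p(d * max(med, 1)^2 / m^2 * 4 + 4 / m)
        while (expected_log_s2(hi, m, Rm, Cm) < target) hi <- hi * 2
        lo <- 0
        for (it in 1:40) {
          mid <- (lo + hi) / 2
          if (expected_log_s2(mid, m, Rm, Cm) < target) lo <- mid else hi <- mid
        }
        s2b <- (lo + hi) / 2
      }
      med <- nb_median(m, m + m^2 * expm1(s2b))
    }
    s2b
  }
  # s2b is a smooth function of the median level alone (d_target follows the
  # trend), so solve on a log-spaced grid and interpolate
  ok <- m_count > 0 & d_target > 0
  out <- numeric(length(m_count))
  if (!any(ok)) return(out)
  lm_all <- log(m_count[ok])
  if (length(unique(lm_all)) <= 48L) {
    grid_lm <- unique(lm_all)
  } else {
    grid_lm <- seq(min(lm_all), max(lm_all), length.out = 48L)
  }
  # representative d at each grid level via monotone interpolation of the
  # supplied (m, d) pairs
  ord <- order(lm_all)
  d_fun <- stats::approxfun(lm_all[ord], log(d_target[ok])[ord], rule = 2,
                            ties = mean)
  grid_s2b <- vapply(grid_lm, function(l) {
    solve_one(exp(l), exp(d_fun(l)))
  }, numeric(1))
  if (length(grid_lm) == 1L) {
    out[ok] <- grid_s2b
  } else {
    out[ok] <- stats::approx(grid_lm, grid_s2b, xout = lm_all, rule = 2,
                             ties = mean)$y
  }
  out
}

#' Ground-truth table for synthetic region signal
#'
#' Draws a cohort of regions with known induction status: a fraction are
#' induced with an onset drawn from the (non-zero) design time points and a
#' fold-change effect size, the rest are stable. Baseline signal levels are
#' log-uniform over `baseline_range`; induced regions draw their baselines
#' from the lower `induced_baseline_range`, reflecting that
#' stimulus-inducible promoters typically carry low pre-stimulation levels
#' of activity and activation marks.
#'
#' @param n_regions Number of regions.
#' @param induced_fraction Fraction of regions that are induced.
#' @param design Time-course design in hours (first point 0).
#' @param effect_range Range of fold-change effect sizes (>= 1) for induced
#'   regions, sampled log-uniformly.
#' @param baseline_range Range of baseline ppm levels for stable regions,
#'   sampled log-uniformly.
#' @param induced_baseline_range Baseline range for induced regions (default
#'   the lower decade of `baseline_range`).
#' @param onset_times Candidate onset times; defaults to the design points
#'   between 1 and 4 h, the window in which stimulus-induced chromatin
#'   changes concentrate.
#' @param feature Feature label carried through to the signal tables.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return A `data.frame` with columns `region_id`, `is_induced`,
#'   `true_induction_time` (NA for stable regions), `effect_size`,
#'   `baseline_ppm`, `feature`.
#' @export
synthetic_truth <- function(n_regions,
                            induced_fraction = 0.2,
                            design = default_design(),
                            effect_range = c(4, 16),
                            baseline_range = c(10, 3000),
                            induced_baseline_range = c(10, 300),
                            onset_times = NULL,
                            feature = "H3K9K14ac",
                            seed = 1L) {
  check_design(design)
  stopifnot(n_regions >= 1, induced_fraction >= 0, induced_fraction <= 1,
            all(effect_range >= 1))
  if (is.null(onset_times)) {
    onset_times <- design[design >= 1 & design <= 4]
    if (length(onset_times) == 0L) onset_times <- design[-1]
  }
  if (!all(onset_times %in% design[-1])) {
    stop("onset_times must be non-zero design time points")
  }
  withr::with_seed(seed, {
    n_ind <- round(n_regions * induced_fraction)
    is_induced <- rep(c(TRUE, FALSE), c(n_ind, n_regions - n_ind))
    onset <- rep(NA_real_, n_regions)
    if (n_ind > 0) {
      onset[is_induced] <- onset_times[sample.int(length(onset_times), n_ind,
                                                  replace = TRUE)]
    }
    effect <- rep(1, n_regions)
    effect[is_induced] <- exp(runif(n_ind, log(effect_range[1]),
                                    log(effect_range[2])))
    baseline <- exp(runif(n_regions, log(baseline_range[1]),
                          log(baseline_range[2])))
    if (n_ind > 0) {
      baseline[is_induced] <- exp(runif(n_ind, log(induced_baseline_range[1]),
                                        log(induced_baseline_range[2])))
    }
    data.frame(
      region_id = sprintf("region_%05d", seq_len(n_regions)),
      is_induced = is_induced,
      true_induction_time = onset,
      effect_size = effect,
      baseline_ppm = baseline,
      feature = feature,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate IP and WCE count tables for a time course
#'
#' Draws per-region, per-time-point counts for the IP sample and its
#' whole-cell-extract (WCE) control. The specific signal of a region follows
#' its baseline, effect size and onset from `truth`; counts are
#' Poisson-lognormal (negative-binomial-like marginals) with the total
#' variance implied by the noise model's quadratic log-dispersion trend,
#' calibrated so the *measured* dispersion of a stable region's series is
#' centred on the trend. The extra-Poisson (biological) component follows a
#' log-scale AR(1) process over the time course (see [noise_model()]), since
#' consecutive samples of a replicate-free course share most of their
#' biological noise. Non-specific background is added to the IP counts and
#' mirrored in the WCE counts; a per-time-point background multiplier
#' (shared across regions, log-normal) emulates sample-to-sample variation
#' in background contamination, which is what the WCE correction downstream
#' is designed to remove. WCE counts are independent of induction status.
#'
#' @param truth Ground-truth table from [synthetic_truth()].
#' @param noise A [noise_model()].
#' @param design Time-course design in hours, strictly increasing from 0.
#' @param seed Integer seed.
#' @param bg_sd Log-scale SD of the per-time-point background multiplier.
#' @return A list with integer matrices `ip` and `wce` (regions x time
#'   points, dimnames from `truth$region_id` and the design), the `design`,
#'   and `depth` (the nominal per-sample depth).
#' @export
simulate_count_series <- function(truth, noise = noise_model(),
                                  design = default_design(), seed = 1L,
                                  bg_sd = 0.4) {
  if (!is.data.frame(truth) || nrow(truth) == 0L) {
    stop("'truth' must be a non-empty data.frame of ground-truth regions")
  }
  check_design(design)
  stopifnot(inherits(noise, "noise_model"))
  if (any(truth$effect_size < 1)) stop("effect sizes must be >= 1")
  if (any(truth$is_induced != !is.na(truth$true_induction_time))) {
    stop("true_induction_time must be present iff is_induced")
  }
  n <- nrow(truth)
  nt <- length(design)
  scale <- noise$count_depth / 1e6

  onset <- ifelse(truth$is_induced, truth$true_induction_time, Inf)
  mu_ppm <- outer(truth$baseline_ppm, rep(1, nt))
  step <- outer(onset, design, FUN = function(o, t) t >= o)
  mu_ppm <- mu_ppm * (1 + (truth$effect_size - 1) * step)
  mu_count <- mu_ppm * scale

  withr::with_seed(seed, {
    if (noise$bio_rho == 0) {
      # independent samples: negative-binomial counts whose variance is
      # calibrated so the measured dispersion follows the trend. The trend
      # maps *median* signal to dispersion and the downstream fit pairs
      # measured medians with measured dispersions, so the dispersion is
      # evaluated at the expected median (one fixed-point pass through the
      # exact negative-binomial median).
      cal <- variance_calibration(nt)
      d0 <- trend_dispersion(pmax(mu_ppm, 1e-12), noise$trend_coefficients)
      med <- nb_median(mu_count, cal * d0 * mu_count^2)
      d_trend <- trend_dispersion(pmax(med / scale, 1e-12),
                                  noise$trend_coefficients)
      kurt_cal <- exp(6 * d_trend / (2 * nt))
      var_count <- cal * kurt_cal * d_trend * med^2
      ip <- matrix(0L, n, nt)
      pos <- mu_count > 0
      size <- ifelse(var_count > mu_count,
                     mu_count^2 / (var_count - mu_count), Inf)
      draw <- numeric(sum(pos))
      finite_size <- is.finite(size[pos])
      mp <- mu_count[pos]
      sp <- size[pos]
      draw[finite_size] <- rnbinom(sum(finite_size), mu = mp[finite_size],
                                   size = sp[finite_size])
      draw[!finite_size] <- rpois(sum(!finite_size), mp[!finite_size])
      ip[pos] <- as.integer(draw)
    } else {
      # autocorrelated biological noise: Poisson counts around a stationary
      # AR(1) log-normal level, calibrated per region at its median level
      med_ppm <- apply(mu_ppm, 1, median)
      d_region <- trend_dispersion(pmax(med_ppm, 1e-12),
                                   noise$trend_coefficients)
      s2b <- calibrate_bio_var(med_ppm * scale, d_region, noise$bio_rho, nt)
      a <- matrix(0, n, nt)
      a[, 1] <- rnorm(n)
      for (j in 2:nt) {
        a[, j] <- noise$bio_rho * a[, j - 1] +
          sqrt(1 - noise$bio_rho^2) * rnorm(n)
      }
      g <- exp(sqrt(s2b) * a - s2b / 2)
      ip <- matrix(rpois(n * nt, mu_count * g), n, nt)
    }

    # per-time-point background multiplier, shared across regions
    bmult <- if (noise$wce_fraction > 0) exp(rnorm(nt, 0, bg_sd)) else rep(0, nt)
    bg_ppm <- outer(noise$wce_fraction * truth$baseline_ppm, bmult)
    ip <- ip + matrix(rpois(n * nt, bg_ppm * scale), n, nt)
    wce <- matrix(rpois(n * nt, bg_ppm * scale), n, nt)

    dimnames(ip) <- dimnames(wce) <- list(truth$region_id,
                                          design_labels(design))
    list(ip = ip, wce = wce, design = design, depth = noise$count_depth)
  })
}

#' Generate a synthetic annotation bundle
#'
#' Places `n_genes` stranded, non-overlapping genes on a single synthetic
#' chromosome and derives exons, 3' UTRs, TSS positions and CpG islands. A
#' configurable fraction of TSSs lie within 1 kb of a CpG island.
#'
#' @param n_genes Number of genes (>= 1).
#' @param chrom_length Chromosome length in bases.
#' @param seed Integer seed.
#' @param cpg_fraction Fraction of genes whose TSS is CpG-island associated.
#' @param gene_length_range Range of gene lengths in bases.
#' @param min_gap Minimum gap between adjacent genes in bases.
#' @param chrom Chromosome name.
#' @return A list of class `synthetic_annotation` with `data.frame` elements
#'   `genes`, `exons`, `utr3`, `cpg_islands` and `tss`, all in 0-based,
#'   half-open coordinates.
#' @export
generate_annotation <- function(n_genes, chrom_length, seed = 1L,
                                cpg_fraction = 0.7,
                                gene_length_range = c(1000, 5000),
                                min_gap = 1000, chrom = "chrS") {
  stopifnot(n_genes >= 1)
  check_scalar_positive(chrom_length, "chrom_length")
  withr::with_seed(seed, {
    len <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                  replace = TRUE)
    needed <- sum(len) + (n_genes - 1) * min_gap
    if (needed > chrom_length) {
      stop(sprintf(
        "infeasible packing: %d genes need %d bases but chrom_length is %d",
        n_genes, needed, as.integer(chrom_length)
      ))
    }
    # distribute leftover space over the n_genes + 1 gaps
    leftover <- chrom_length - needed
    cuts <- sort(runif(n_genes))
    extra <- floor(leftover * diff(c(0, cuts, 1)))
    gaps <- c(extra[1], extra[-1] + c(rep(min_gap, n_genes - 1), 0))
    start <- cumsum(gaps[seq_len(n_genes)]) + c(0, cumsum(len))[seq_len(n_genes)]
    end <- start + len
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    genes <- data.frame(chrom = chrom, start = start, end = end,
                        strand = strand, gene_id = gene_id,
                        stringsAsFactors = FALSE)

    # exons: split each gene into 1-3 exons separated by introns
    exon_list <- lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(1:3, 1)
      if (n_ex == 1L || len[i] < 900) {
        data.frame(chrom = chrom, start = start[i], end = end[i],
                   strand = strand[i], gene_id = gene_id[i],
                   stringsAsFactors = FALSE)
      } else {
        # breakpoints at least 100 bp apart; alternate exon/intron
        k <- 2 * (n_ex - 1)
        bp <- sort(sample(seq(start[i] + 100, end[i] - 100, by = 50), k))
        bounds <- c(start[i], bp, end[i])
        ex_start <- bounds[seq(1, length(bounds) - 1, by = 2)]
        ex_end <- bounds[seq(2, length(bounds), by = 2)]
        data.frame(chrom = chrom, start = ex_start, end = ex_end,
                   strand = strand[i], gene_id = gene_id[i],
                   stringsAsFactors = FALSE)
      }
    })
    exons <- do.call(rbind, exon_list)

    # 3' UTR: terminal slice of the gene on its own strand
    utr_len <- pmin(500L, floor(len * 0.2))
    utr3 <- data.frame(
      chrom = chrom,
      start = ifelse(strand == "+", end - utr_len, start),
      end = ifelse(strand == "+", end, start + utr_len),
      strand = strand, gene_id = gene_id, stringsAsFactors = FALSE
    )

    tss_pos <- ifelse(strand == "+", start, end - 1L)
    tss <- data.frame(chrom = chrom, pos = tss_pos, strand = strand,
                      gene_id = gene_id, stringsAsFactors = FALSE)

    n_cpg <- round(cpg_fraction * n_genes)
    cpg_genes <- sort(sample(seq_len(n_genes), n_cpg))
    cpg <- data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      stringsAsFactors = FALSE
    )
    if (n_cpg > 0) {
      cpg <- data.frame(
        chrom = chrom,
        start = pmax(0L, tss_pos[cpg_genes] - 250L),
        end = pmin(as.integer(chrom_length), tss_pos[cpg_genes] + 250L),
        stringsAsFactors = FALSE
      )
    }
    structure(
      list(genes = genes, exons = exons, utr3 = utr3, cpg_islands = cpg,
           tss = tss, chrom = chrom, chrom_length = as.integer(chrom_length)),
      class = "synthetic_annotation"
    )
  })
}

#' @export
print.synthetic_annotation <- function(x, ...) {
  cat(sprintf(
    "Synthetic annotation: %d genes on %s (%d bp), %d exons, %d CpG islands\n",
    nrow(x$genes), x$chrom, x$chrom_length, nrow(x$exons), nrow(x$cpg_islands)
  ))
  invisible(x)
}

#' Simulate strand-specific TSS-seq 5'-end reads
#'
#' Transcription in many promoters initiates preferentially at one or a few
#' bases; the generator concentrates a configurable fraction of a promoter's
#' reads on its dominant initiation base and scatters the remainder within a
#' small window. Read counts per promoter are Poisson with mean proportional
#' to the promoter's activity at each time point; read strand matches the
#' gene strand.
#'
#' @param promoters `data.frame` with columns `gene_id`, `chrom`, `tss`
#'   (0-based base position) and `strand`.
#' @param activity Matrix (promoters x time points) of activity in ppm;
#'   must be non-negative.
#' @param design Time-course design in hours.
#' @param seed Integer seed.
#' @param dominant_fraction Expected fraction of reads on the dominant base.
#' @param spread Half-width in bases of the scatter window for non-dominant
#'   reads.
#' @param count_depth Library depth used to convert ppm to expected reads.
#' @return `data.frame` with columns `time`, `chrom`, `position`, `strand`,
#'   `count` (aggregated per base). Zero activity everywhere yields a table
#'   with zero rows.
#' @export
simulate_tss_reads <- function(promoters, activity, design = default_design(),
                               seed = 1L, dominant_fraction = 0.6,
                               spread = 10L, count_depth = 1e6) {
  check_design(design)
  if (any(activity < 0)) stop("activity must be non-negative")
  stopifnot(nrow(promoters) == nrow(activity),
            ncol(activity) == length(design),
            dominant_fraction >= 0, dominant_fraction <= 1)
  withr::with_seed(seed, {
    out <- vector("list", length(design))
    offsets <- setdiff(-spread:spread, 0L)
    for (j in seq_along(design)) {
      n_reads <- rpois(nrow(promoters), activity[, j] * count_depth / 1e6)
      rows <- which(n_reads > 0)
      if (length(rows) == 0L) next
      tabs <- lapply(rows, function(i) {
        n <- n_reads[i]
        n_dom <- rbinom(1, n, dominant_fraction)
        pos <- rep(promoters$tss[i], n_dom)
        if (n > n_dom) {
          pos <- c(pos, promoters$tss[i] +
                     sample(offsets, n - n_dom, replace = TRUE))
        }
        tab <- table(pos)
        data.frame(
          time = design[j], chrom = promoters$chrom[i],
          position = as.integer(names(tab)),
          strand = promoters$strand[i],
          count = as.integer(tab), stringsAsFactors = FALSE
        )
      })
      out[[j]] <- do.call(rbind, tabs)
    }
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(time = numeric(0), chrom = character(0),
                        position = integer(0), strand = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
    }
    res <- res[order(res$time, res$chrom, res$strand, res$position), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
  })
}

#' Simulate TF ChIP-seq peak-score tables
#'
#' Emulates per-TF, per-time-point peak tables with a score threshold for
#' significant binding: target regions carry scores above the threshold from
#' their binding-onset time onward and sub-threshold (or absent) scores
#' before; non-target decoy peaks never exceed the threshold.
#'
#' @param binding_truth `data.frame` with columns `tf`, `region_id`, `chrom`,
#'   `start`, `end`, `onset_time` (NA for regions the TF never binds).
#' @param time_points Time points at which the TF was assayed (hours).
#' @param threshold Score threshold for significant binding.
#' @param seed Integer seed.
#' @param sub_peak_prob Probability that a not-yet-bound target or a
#'   non-target carries a sub-threshold peak (rather than no peak).
#' @return List with `peaks` (`data.frame`: `chrom`, `start`, `end`, `score`,
#'   `tf`, `time`) and `threshold`.
#' @export
simulate_tf_peaks <- function(binding_truth, time_points = c(0, 0.5, 1, 2),
                              threshold = 50, seed = 1L,
                              sub_peak_prob = 0.5) {
  stopifnot(is.data.frame(binding_truth), nrow(binding_truth) > 0)
  ok_onset <- is.na(binding_truth$onset_time) |
    binding_truth$onset_time %in% time_points
  if (!all(ok_onset)) stop("onset times must be drawn from 'time_points'")
  withr::with_seed(seed, {
    rows <- vector("list", length(time_points) * nrow(binding_truth))
    k <- 0L
    for (t in time_points) {
      for (i in seq_len(nrow(binding_truth))) {
        b <- binding_truth[i, ]
        bound <- !is.na(b$onset_time) && t >= b$onset_time
        if (bound) {
          score <- threshold * runif(1, 1.2, 3)
        } else if (runif(1) < sub_peak_prob) {
          score <- threshold * runif(1, 0.1, 0.8)
        } else {
          next
        }
        k <- k + 1L
        rows[[k]] <- data.frame(
          chrom = b$chrom, start = b$start, end = b$end, score = score,
          tf = b$tf, time = t, stringsAsFactors = FALSE
        )
      }
    }
    peaks <- if (k > 0) do.call(rbind, rows[seq_len(k)]) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 score = numeric(0), tf = character(0), time = numeric(0),
                 stringsAsFactors = FALSE)
    rownames(peaks) <- NULL
    list(peaks = peaks, threshold = threshold)
  })
}

#' Scatter region counts into read-position tables
#'
#' Turns per-region count matrices (e.g. from [simulate_count_series()]) into
#' per-time-point read-position tables by placing each region's reads
#' uniformly within its interval, optionally adding genome-wide background
#' reads. Used to exercise the counting step of [quantify()].
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` aligned with the
#'   rows of `counts`.
#' @param counts Integer matrix (regions x time points).
#' @param design Time-course design (hours), one column per design point.
#' @param chrom_length Chromosome length for background reads.
#' @param bg_reads Expected number of genome-wide background reads per sample.
#' @param seed Integer seed.
#' @return A list (one element per time point, named by design label) of
#'   `data.frame`s with `chrom`, `position`, `count`.
#' @export
scatter_reads <- function(regions, counts, design = default_design(),
                          chrom_length = NULL, bg_reads = 0, seed = 1L) {
  stopifnot(nrow(regions) == nrow(counts), ncol(counts) == length(design))
  withr::with_seed(seed, {
    out <- vector("list", length(design))
    names(out) <- design_labels(design)
    for (j in seq_along(design)) {
      pos_list <- lapply(seq_len(nrow(regions)), function(i) {
        n <- counts[i, j]
        if (n == 0L) return(NULL)
        sample(regions$start[i]:(regions$end[i] - 1L), n, replace = TRUE)
      })
      chroms <- rep(regions$chrom, vapply(pos_list, length, integer(1)))
      pos <- unlist(pos_list)
      if (bg_reads > 0) {
        if (is.null(chrom_length)) stop("chrom_length needed for background")
        nb <- rpois(1, bg_reads)
        pos <- c(pos, sample.int(chrom_length, nb, replace = TRUE) - 1L)
        chroms <- c(chroms, rep(regions$chrom[1], nb))
      }
      if (length(pos) == 0L) {
        out[[j]] <- data.frame(chrom = character(0), position = integer(0),
                               count = integer(0), stringsAsFactors = FALSE)
        next
      }
      dt <- data.table::data.table(chrom = chroms, position = as.integer(pos))
      agg <- dt[, list(count = .N), by = c("chrom", "position")]
      data.table::setorder(agg, chrom, position)
      out[[j]] <- as.data.frame(agg)
    }
    out
  })
}
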