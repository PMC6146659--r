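test_that("region statistics use the median and population standard deviation", {
  const <- matrix(5, 1, 10)
  st <- region_stats(const)
  expect_equal(st$m, 5)
  expect_equal(st$s, 0)
  expect_equal(st$d, 0)

  x <- matrix(1:10, 1, 10)
  st <- region_stats(x)
  expect_equal(st$m, 5.5)
  expect_equal(st$s, sqrt(mean((1:10 - 5.5)^2)))  # divide by n
  expect_equal(st$d, (st$s / 5.5)^2)

  zero <- matrix(0, 1, 10)
  expect_true(is.na(region_stats(zero)$d))
})

test_that("the quadratic trend fit is exact on noiseless data and excludes m = 0", {
  m <- 10^seq(0.5, 3.5, length.out = 50)
  d <- 10^(0.7 - 1.3 * log10(m) + 0.11 * log10(m)^2)
  stats_df <- data.frame(region_id = as.character(seq_along(m)), m = m,
                         s = m * sqrt(d), d = d)
  fit <- fit_dispersion_trend(stats_df, feature = "f")
  expect_equal(unname(coef(fit)), c(0.7, -1.3, 0.11), tolerance = 1e-9)

  # adding an m = 0 region leaves the fit unchanged
  with_zero <- rbind(stats_df,
                     data.frame(region_id = "z", m = 0, s = 0, d = NA))
  fit2 <- fit_dispersion_trend(with_zero, feature = "f")
  expect_equal(coef(fit2), coef(fit))
  expect_equal(fit2$support, 50L)

  expect_error(fit_dispersion_trend(stats_df[1:2, ]), "at least 3")
})

test_that("dispersion_trend is a full-featured model object", {
  noise <- noise_model(wce_fraction = 0)
  truth <- synthetic_truth(500, induced_fraction = 0, seed = 2)
  cs <- simulate_count_series(truth, noise, seed = 102)
  sig <- region_signal(cs$ip * 1e6 / noise$count_depth)
  fit <- fit_dispersion_trend(sig, feature = "H3K9K14ac")

  expect_s3_class(fit, "dispersion_trend")
  expect_named(coef(fit), c("a0", "a1", "a2"))
  expect_output(print(fit), "Mean-dispersion trend")
  sm <- summary(fit)
  expect_output(print(sm), "R\\^2")
  expect_gt(sm$r_squared, 0.5)

  pred <- predict(fit, c(10, 100, 1000))
  expect_equal(pred$sd_fitted, pred$m * sqrt(pred$dispersion))
  expect_error(predict(fit, c(-1, 10)), "positive")
  expect_equal(length(residuals(fit)), fit$support)

  simd <- simulate(fit, nsim = 2, seed = 4, median_ppm = c(100, 400),
                   n_time = 10)
  expect_equal(dim(simd), c(4L, 10L))
  expect_true(all(simd >= 0))

  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("vectorized Z-scores equal the scalar re-implementation", {
  set.seed(17)
  n <- 1000
  ppm <- matrix(rexp(n * 10, rate = 1 / 100), n, 10)
  ppm[sample(n, 5), ] <- 0  # undefined rows
  rownames(ppm) <- sprintf("r%04d", seq_len(n))
  fit <- structure(
    list(coefficients = c(a0 = 0.6, a1 = -1.4, a2 = 0.1),
         feature = "f"),
    class = "dispersion_trend"
  )
  z <- z_scores(ppm, fit)
  oracle <- bf_z_scores(ppm, c(0.6, -1.4, 0.1))
  expect_equal(unname(z), oracle, tolerance = 1e-9)
  # Z at 0 h is exactly zero wherever defined
  expect_true(all(z[!is.na(z[, 1]), 1] == 0))
})

test_that("Z-scores are linear in the signal shift and monotone per time point", {
  fit <- structure(
    list(coefficients = c(a0 = 0, a1 = -1, a2 = 0), feature = "f"),
    class = "dispersion_trend"
  )
  base <- matrix(100, 1, 10)
  # s_fitted = m * sqrt(10^(0 - log10(m))) = sqrt(m) = 10
  shifted <- base
  shifted[1, 5] <- 100 + 2 * 10
  z <- z_scores(shifted, fit)
  expect_equal(z[1, 5], 2)

  # raising one time point never lowers its Z (fit and baseline held fixed)
  z_lo <- z_scores(shifted, fit)
  shifted[1, 5] <- shifted[1, 5] + 7
  z_hi <- z_scores(shifted, fit)
  expect_gt(z_hi[1, 5], z_lo[1, 5])
})

test_that("induction calls apply the Z and low-signal rules jointly", {
  design <- default_design()
  fit <- structure(
    list(coefficients = c(a0 = 0, a1 = -1, a2 = 0), feature = "f"),
    class = "dispersion_trend"
  )
  # s_fitted = sqrt(m); build series with known Z patterns
  mk <- function(z_vec, level = 100) {
    m <- matrix(level, 1, 10)
    m[1, ] <- level + z_vec * sqrt(level)
    m
  }
  # max Z = 3.9: not significant
  below <- mk(c(0, 0, 0, 0, 0, 0, 0, 0, 0, 3.9))
  calls <- call_induction(below, fit, design, low_signal_cut = 1)
  expect_false(calls$significant)

  # Z crosses 2 at 1 h and 4 later: significant with induction time 1 h
  rising <- mk(c(0, 1, 2.5, 5, 5, 5, 5, 5, 5, 5))
  calls <- call_induction(rising, fit, design, low_signal_cut = 1)
  expect_true(calls$significant)
  expect_equal(calls$induction_time, 1)
  expect_gte(calls$max_z, 4)

  # Z >= 4 but every ppm below the cut: filtered out
  calls <- call_induction(rising, fit, design, low_signal_cut = 1e6)
  expect_false(calls$significant)

  # all-zero region: undefined Z, never significant
  zero <- matrix(0, 1, 10)
  calls <- call_induction(zero, fit, design, low_signal_cut = 1)
  expect_false(calls$significant)
})

test_that("LPS-induced and unchanged promoter rules follow their thresholds", {
  design <- default_design()
  fit <- structure(
    list(coefficients = c(a0 = 0, a1 = -1, a2 = 0), feature = "TSS"),
    class = "dispersion_trend"
  )
  flat <- matrix(50, 3, 10)
  flat[2, 6:10] <- 50 + 5 * sqrt(50)   # strong step at 4 h
  flat[3, 6:10] <- 50 - 1.2 * sqrt(50) # dip below -1
  rownames(flat) <- c("p1", "p2", "p3")
  calls <- call_lps_induced_promoters(flat, fit, design)
  expect_equal(calls$significant, c(FALSE, TRUE, FALSE))
  expect_equal(calls$induction_time[2], 4)

  z <- attr(calls, "z")
  unchanged <- call_unchanged_promoters(z)
  expect_equal(unchanged, c(TRUE, FALSE, FALSE))

  # ppm filter: a promoter that never reaches 1 ppm is not induced
  weak <- matrix(0.01, 1, 10)
  weak[1, 6:10] <- 0.01 + 5 * sqrt(0.01)
  calls_weak <- call_lps_induced_promoters(weak, fit, design)
  expect_false(calls_weak$significant)

  # brute-force scan of the unchanged rule on random promoters
  set.seed(23)
  zr <- matrix(rnorm(1000 * 10, sd = 0.8), 1000, 10)
  zr[, 1] <- 0
  got <- call_unchanged_promoters(zr)
  brute <- vapply(seq_len(nrow(zr)), function(i) all(abs(zr[i, ]) < 1),
                  logical(1))
  expect_equal(got, brute)
})

test_that("basal-level classes split absent/low/high deterministically", {
  expect_equal(as.character(basal_level_classes(c(0, 1, 2, 3, 4))),
               c("absent", "low", "low", "high", "high"))
  expect_equal(as.character(basal_level_classes(c(1, 2, 3))),
               c("low", "low", "high"))
  expect_equal(as.character(basal_level_classes(0)), "absent")
  # ties broken by region id
  cls <- basal_level_classes(c(2, 2), region_id = c("b", "a"))
  expect_equal(as.character(cls), c("high", "low"))
})

test_that("knockout dependence uses the five-fold rule with pseudocounts", {
  wt <- matrix(c(1, 12, 12, 1, 12, 12), 2, 3, byrow = TRUE)
  ko <- matrix(c(1, 2, 2, 1, 3, 3), 2, 3, byrow = TRUE)
  dep <- ko_dependence(wt, ko, epsilon = 0)
  expect_equal(dep$dependent, c(TRUE, FALSE))  # 12 > 10; 12 < 15

  # synthetic pathway knockout: ablated genes recovered at >= 95%
  set.seed(29)
  n <- 400
  base <- rexp(n, 1 / 5) + 0.5
  fold <- exp(runif(n, log(8), log(40)))
  dependent_truth <- rep(c(TRUE, FALSE), each = n / 2)
  mk_series <- function(active) {
    t(vapply(seq_len(n), function(i) {
      peak <- if (active[i]) base[i] * fold[i] else base[i]
      mu <- c(base[i], peak, peak, base[i] * 1.1)
      mu * exp(rnorm(4, 0, 0.1))
    }, numeric(4)))
  }
  wt_series <- mk_series(rep(TRUE, n))
  ko_series <- mk_series(!dependent_truth)
  dep <- ko_dependence(wt_series, ko_series, epsilon = 0.1)
  sens <- mean(dep$dependent[dependent_truth])
  fpr <- mean(dep$dependent[!dependent_truth])
  expect_gte(sens, 0.95)
  expect_lte(fpr, 0.05)
})
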