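# chipcourse

Induction-time analysis of time-course ChIP-seq and TSS-seq signals at
promoters and enhancers, without replicates.

## The problem

Stimulation time courses (e.g. dendritic cells responding to LPS) are often
profiled with one ChIP-seq library per time point per feature — ten time
points from 0 to 24 h for each histone modification, Pol2, and TSS-seq —
and no replicates. At every promoter and enhancer the analysis must decide
whether a feature shows a significant increase over its 0 h baseline and at
which time point the increase first appears, then relate those induction
times to transcription-factor binding dynamics. `chipcourse` implements the
full chain for this design: signal quantification, promoter and enhancer
definition, the replicate-free significance model, and TF association,
plus a synthetic-data generator with known ground truth that makes every
stage testable.

## The model

For region *x* and feature *f* over the design time points, with median
*m* and population standard deviation *s* of the ppm series, the
dispersion is the squared coefficient of variation

    d = (s / m)^2

A quadratic trend `log10(d) = a0 + a1*log10(m) + a2*log10(m)^2` is fit by
least squares across **all** promoter and enhancer regions of a dataset,
giving each region a trend-implied standard deviation
`s_fitted = m * sqrt(d_fitted)`. Deviations from baseline are scored as

    Z_t = (ppm_t - ppm_0h) / s_fitted

A region is significantly induced if `Z >= 4` at some time point and its
ppm passes a low-signal filter (the feature's 25th percentile of non-zero
values); its induction time is the first time point with `Z >= 2`.
Stimulus-induced promoters apply the same rule to sense-strand TSS-seq ppm
with a floor of 1 ppm; unchanged promoters have `|Z| < 1` throughout.

Around the model: control-swap FDR thresholding of peak calls (FDR 0.01),
500-bp region merging, whole-cell-extract background correction, RPKM →
quantile normalization → ppm conversion; a multi-scale scanning-window TSS
caller against a randomized null (FDR 0.001); enhancer definition by
H3K4me1-high/H3K4me3-low filters with nearest-promoter assignment within
150 kb; and TF-binding association via two-sided Fisher exact tests,
binding-site metaprofiles, and induction-timing curves.

## Worked example

Simulate a cohort with known ground truth (2000 stable regions, 500
induced with fold changes of 4–16× and onsets between 1 and 4 h), correct
for background, fit the dispersion trend, and call inductions:

```r
library(chipcourse)

noise  <- noise_model()
stable  <- synthetic_truth(2000, induced_fraction = 0, seed = 1)
induced <- synthetic_truth(500, induced_fraction = 1, seed = 51)
induced$region_id <- sprintf("ind_%05d", 1:500)
truth  <- rbind(stable, induced)

counts <- simulate_count_series(truth, noise, seed = 101)
ppm <- correct_counts(counts$ip, counts$wce,
                      noise$count_depth, noise$count_depth) *
  1e6 / noise$count_depth

fit <- fit_dispersion_trend(ppm, feature = "H3K9K14ac")
fit
#> Mean-dispersion trend for feature 'H3K9K14ac'
#>   log10(d) = 0.2173 -0.9520*log10(m) +0.0978*log10(m)^2
#>   fitted on 2500 regions (of 2500)

calls <- call_induction(ppm, fit, design = counts$design)
calls
#> induction_calls: 2500 regions, feature 'H3K9K14ac'; 502 significant (20.08%)
#>   induction times (h):  0.5 h: 1, 1 h: 122, 2 h: 138, 3 h: 119, 4 h: 121, 8 h: 1
```

The fitted trend differs from the generator's nominal coefficients because
the cohort contains the induced minority, exactly as a genome-wide fit
does. Of the 502 calls, 496 are true inductions and 6 are false positives:

```r
mean(calls$significant[truth$is_induced])    # sensitivity
#> [1] 0.992
mean(calls$significant[!truth$is_induced])   # false-positive rate
#> [1] 0.003
```

`fit` is an ordinary model object: `summary()`, `coef()`, `predict()`
(fitted dispersion and SD at new median levels), `plot()` (the
mean-dispersion cloud with the fitted curve), `residuals()` and
`simulate()` all work. `run_pipeline(pipeline_config(seed = 1))` executes
the whole chain — simulation, quantification, promoter and enhancer
calling, induction calling, TF association — into a directory of TSV
artifacts with a hashed manifest.

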