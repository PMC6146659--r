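---
title: "Calling stimulus-induced chromatin changes without replicates: the dispersion-trend Z-score model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling stimulus-induced chromatin changes without replicates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcourse)
```

## The problem

A stimulation time course measured by ChIP-seq (histone modifications, Pol2)
and TSS-seq typically has one sample per time point and no replicates: ten
libraries covering 0 to 24 hours, for each of several features. The question
at every promoter and enhancer is whether a feature shows a genuine increase
over its pre-stimulation (0 h) level and, if so, *when* the increase first
appears. Without replicates the variance at a given region cannot be
estimated from repeated measurements, and naive fold-change thresholds are
dominated by the high relative noise of weak regions.

The model implemented here borrows the central idea of count-based
differential-expression methods (a mean-variance trend pooled across
features) and adapts it to a replicate-free time series of
reads-per-million (ppm) values.

## The model

For a region $x$ and feature $f$, with ppm values over the $n$ design time
points, define

$$d_{x,f} = \left(\frac{s_{x,f}}{m_{x,f}}\right)^2,$$

where $m_{x,f}$ is the median and $s_{x,f}$ the population standard
deviation (dividing by $n$) of the series. This dispersion — a squared
coefficient of variation — is dominated by sampling noise for stable regions
and decreases systematically with signal strength. Pooling *all* promoter
and enhancer regions of a dataset, a quadratic trend

$$\log_{10} d = a_0 + a_1 \log_{10} m + a_2 (\log_{10} m)^2$$

is fit by least squares over regions with $m > 0$ and $d > 0$
(`fit_dispersion_trend()`). The trend-implied standard deviation
$s_{\mathrm{fitted}} = m\sqrt{d_{\mathrm{fitted}}}$ then scales deviations
from baseline into Z-scores:

$$Z_{x,f,t} = \frac{\mathrm{ppm}_{x,f,t} - \mathrm{ppm}_{x,f,0h}}{s_{x,f,\mathrm{fitted}}}.$$

A region is *significantly induced* if $Z \ge 4$ at some time point **and**
its ppm reaches the feature's low-signal cut (the 25th percentile of
non-zero ppm values over all regions and time points) at some time point.
For significant regions the *induction time* is the first time point with
$Z \ge 2$. Stimulus-induced promoters use the same rule on sense-strand
TSS-seq signal with an absolute floor of 1 ppm; *unchanged* promoters have
$|Z| < 1$ everywhere.

Two conventions must be fixed because the Z cutoffs are absolute. First,
the standard deviation in the dispersion is the population form (divide by
$n$): the ten points are treated as the complete series, and any constant
factor is absorbed by the trend in the same units. Second, the trend is
refit per feature and per dataset, so a shorter course (the 0/1/2/4 h
replicate design, or a 0/4 h knockout comparison) gets its own fit rather
than inheriting one estimated under a different design length.

Why the significance rule works: the fitted trend passes through the centre
of the dispersion cloud of *all* regions. Since that cloud contains the
genuinely dynamic minority, the trend sits above the sampling noise of a
truly stable region, and a four-standard-deviation excursion from baseline
is rare under stability. The low-signal percentile filter removes the weak
regions whose Z-scores are least reliable. Note that for independent noise
the Z threshold alone is not a per-region p-value cutoff — the baseline is
itself noisy, and the one-sided tail of `max(Z)` over nine post-baseline
points would be a few percent if the trend tracked stable noise exactly.
The false-positive control demonstrated by the tests (below 1%) therefore
depends on the composition of the region set, which is why the trend is
always fit on the full promoter-plus-enhancer cohort, never on a curated
stable subset.

## The processing chain around the model

`quantify()` produces the ppm matrix the model consumes:

1. **Peak thresholding** (`fdr_threshold_peaks()`): peak calls from an
   external caller run in both orientations (IP vs control, control vs IP)
   are thresholded at the smallest score where the control-to-true tail
   ratio drops to the target FDR (0.01), per time point.
2. **Region merging** (`merge_regions()`): retained peaks from all time
   points are merged; intervals separated by fewer than 500 bases join the
   same region. Coordinates are 0-based half-open throughout, and two
   half-open intervals `[a,b)`, `[c,d)` merge iff `c - b < 500`.
3. **Background correction** (`correct_counts()`): the expected number of
   non-specific reads (the WCE count rescaled by the library-depth ratio)
   is subtracted from each region's IP count, floored at zero since the
   corrected value estimates a count.
4. **Normalization**: corrected counts become RPKM, are quantile-normalized
   across the time points of the feature (assuming the genome-wide signal
   distribution is stable over the course), and return to the ppm scale via
   `ppm = rpkm * length / 1000`. The last step is the only unit-consistent
   reading of a per-region per-million quantity; ties in the quantile
   normalization receive the mean reference value at their rank positions.

Promoters come from a strand-specific scanning-window caller
(`scan_windows()`, `call_significant_windows()`): windows of 1, 10, 50,
100, 500 and 1000 bases advanced in steps of 1, 1, 5, 10, 50 and 100 are
scored by contained TSS-seq 5' ends and compared against an
alignment-count-matched uniform null (`build_null()`) at FDR 0.001 per
window size; overlapping survivors keep the lowest empirical FDR (ties:
higher count, then smaller window). Candidates inside 3' UTRs or more than
50 kb upstream of every same-strand gene are removed; within a candidate
the representative TSS is the base with the maximal count (ties resolve
5'-ward); candidates without Pol2 or H3K4me3 evidence within 1 kb are
discarded as TSS-seq-only noise; each gene keeps its strongest candidate,
and genes without one receive their annotation TSS when the 2-kb window is
free (`supplement_refseq()`). The published analysis selected
representative TSSs with a model whose full specification is not in the
main text; the three explicit criteria above approximate it and are the
documented behaviour here.

Enhancers are H3K4me1-significant merged regions at least 2 kb away from
promoter windows and exons, at most 10 kb long, with time-summed H3K4me1 at
least five times time-summed H3K4me3. The ratio uses time-aggregated
signal: the source analysis does not state the time point, and aggregation
is stable against single-sample noise while matching the
"significant in at least one time point" selection. Each enhancer is
assigned to the nearest promoter within 150 kb centre-to-centre
(`assign_to_promoter()`).

TF association (`bound_regions()`, `new_binding_events()`,
`overlap_fisher()`, `binding_site_profile()`, `timing_fraction_curves()`)
defines binding by peak-score threshold overlap with the analysis window
(TSS ± 1 kb; enhancer interval, or centre ± 1 kb when under 2 kb), calls a
new-binding event at the first significant time point with all earlier
*available* points non-significant (a region bound at its earliest
available point is pre-bound and yields no event), and tests binding ×
increase overlap with the two-sided Fisher exact test, reported as
$-\log_{10} p$ for heatmaps. Metaprofile anchors are peak midpoints — the
only coordinate every peak table provides — with half-open 100-bp bins.

## The synthetic-data generator

Every stage is validated against `synthetic_truth()` /
`simulate_count_series()` cohorts with known ground truth. The generator's
defaults are the study conditions, chosen once:

* **Design**: the ten-point course 0, 0.5, 1, 2, 3, 4, 6, 8, 16, 24 h.
* **Noise trend**: $(a_0, a_1, a_2) = (1, -1.8, 0.25)$ on the log10 scale.
  This gives coefficients of variation falling from about 0.5 at 10 ppm to
  0.08 at 3000 ppm — a realistic ChIP-seq profile whose curvature
  (flattening toward high signal) is large enough to be identifiable: at
  the 5000-region scale used for parameter-recovery checks, each
  coefficient's magnitude is several times its regression standard error,
  so a ±10% recovery requirement is a test of correctness rather than of
  luck.
* **Baselines**: log-uniform over 10–3000 ppm for stable regions, 10–300
  ppm for induced regions. The low-basal induced range reflects the
  biology of inducible promoters — stimulus-responsive genes carry low
  pre-stimulation levels of activity marks — and keeps induced medians
  inside the signal range dominated by stable regions, so the pooled trend
  fit is not distorted at its upper end.
* **Effects and onsets**: fold changes log-uniform in 4–16×, onsets among
  the 1–4 h design points (the window where stimulus-induced chromatin
  changes concentrate), applied as a step in the mean.
* **Counts**: negative binomial (Poisson when at or below the Poisson
  floor), depth $10^6$ reads per sample. The generated variance is
  calibrated so that the *measured* dispersion — population variance over
  the finite series divided by the squared sample median — is centred on
  the nominal trend. The calibration compensates three estimator biases:
  the $(n-1)/n$ factor of the population variance, the chi-square Jensen
  term of the log, and the offset between the mean and the median of a
  skewed count distribution (evaluated through the exact negative-binomial
  median). Without it, recovered trend intercepts would be biased low by
  roughly 0.1 log10 units — a property of the estimator, not of the data.
  An optional mode (`bio_rho > 0`) makes the extra-Poisson component a
  log-scale AR(1) process for experiments on temporally correlated noise;
  it is off by default because the independent-sample model is the
  documented contract.
* **Background**: non-specific signal at 10% of baseline, with a
  per-time-point log-normal multiplier shared across regions — the
  sample-to-sample contamination wobble that WCE correction exists to
  remove. WCE counts are independent of induction status.

What the generator deliberately does **not** emulate: mappability and
GC-bias structure, fragment-length effects, copy-number variation, raw
read sequences, and temporal autocorrelation of biological noise (by
default). Passing tests therefore demonstrate the correctness and
calibration of the *procedure* under its stated noise assumptions, not
performance on any particular real dataset.

## Numerical and degenerate-input choices

* Regions with zero median are excluded from the trend fit and are never
  significant (their Z is undefined); an all-zero matrix raises no error.
* A quantile-normalized matrix needs at least one region and two columns; a
  single-region matrix is forced to a flat series by construction, which is
  the mathematically consistent (if degenerate) behaviour.
* Basal-level classes split non-zero regions into equal halves after
  sorting by level with region-id tie-breaks; an odd count puts the extra
  region in the low class.
* Knockout dependence uses a pseudocount of 0.1 RPKM in the fold-change
  ratio; the dependence calls of clearly induced genes are insensitive to
  this value within an order of magnitude (the tests exercise the rule at
  ablated-vs-intact effect sizes far from the 5× boundary).
* All randomness flows through explicit integer seeds; the caller's RNG
  state is saved and restored.

## Problem sizes

The bundled checks run at desk scale, chosen to finish in minutes while
leaving the statistical margins wide: 5000 stable regions for trend
recovery, 2000 stable + 500 induced for the caller's operating
characteristics, 30,000 reads on a 1-Mb toy genome for scanning-window
calibration, and a 1000-region cohort for the end-to-end regulator
scenario. Headline counts from genome-scale datasets (tens of thousands of
promoters and enhancers) are not reproducible at this scale and are used
only as worked-example ratios.

## Limitations

* The model detects increases only; decreases are outside its definition.
* Fixed Z cutoffs are not multiplicity-adjusted p-values; they are
  calibrated operating points inherited from the published procedure.
* The representative-TSS selection is an approximation of the original
  (partially unpublished) selection model.
* With two-point designs the dispersion degenerates; the per-dataset refit
  keeps the machinery defined, but Z-scores from two points carry little
  information and knockout comparisons should lean on the fold-change rule.
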