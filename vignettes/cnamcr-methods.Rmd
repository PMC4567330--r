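---
title: "Methods: interval-score CNA detection and minimal common regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interval-score CNA detection and minimal common regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cnamcr` implements a complete tumor/normal array-CGH copy-number workflow:
per-array normalization, interval-score aberration calling, cross-sample
common-aberration statistics, recurrent-region (CNAR/MCR) extraction across
array platforms, MLPA validation calling, qPCR expression association, and
clinicopathological statistics. This vignette records the model, the
parameter choices, and the design decisions, so that every number the
package produces can be traced to a stated rule.

## The measurement model

A two-channel aCGH probe reports the log2 ratio of tumor to matched-normal
DNA at a genomic interval. A diploid (copy-number 2) locus has expected
log2(2/2) = 0; a single-copy gain in a pure tumor has log2(3/2) ≈ 0.58 and
a single-copy loss log2(1/2) = −1. Observed values deviate from this ideal
through (i) probe-level noise, (ii) a smooth dye/intensity trend within each
array, and (iii) a global per-array baseline shift. The normalization stack
addresses exactly these three terms, in order:

1. **Within-array lowess** (`lowess_correct()`): a robust locally weighted
   regression of log2 ratio on the probe's log10 channel intensity is
   subtracted. The fitted curve is mean-centered first, so the stage removes
   curvature but never moves the global level. Default span 0.3; the stage
   is skippable for inputs that carry no intensity covariate.
2. **Between-array quantile normalization** (`quantile_normalize()`,
   delegated to `limma::normalizeQuantiles` with tie averaging): each
   array's order statistics are replaced by the across-array mean, per
   platform. Ranks within an array never change.
3. **Centralization** (`centralize()`): the mode of the log2 distribution —
   the copy-neutral state, as long as most of the genome is diploid — is
   estimated by a Gaussian kernel density (Silverman bandwidth by default)
   and subtracted. If two modes tie in height the one nearer zero wins,
   with a warning, since the diploid state is the prior expectation.

Per-array noise is estimated by the derivative log-ratio spread
(`estimate_probe_noise()`): successive probe differences within chromosomes,
`sigma = 1.4826 * MAD(d) / sqrt(2)`, floored at 1e−6. A genuine copy-number
step contributes only a handful of outlying differences among thousands, so
the estimate is insensitive to the signal it will later help detect.

## Aberration calling

Detection uses the interval-score statistic behind ADM-style algorithms:

$$S(i,j) = \frac{\left|\sum_{k=i}^{j} r_k\right|}{\sigma\sqrt{j-i+1}}$$

A run of probes with mean m scores |m|·sqrt(n)/σ, so evidence accumulates
with length at fixed amplitude. Per chromosome the maximum-score interval is
extracted greedily; if it reaches the threshold (default 6.0) it is recorded
and the search recurses on the flanks. Ties are broken toward the leftmost,
then shortest interval. Sums are signed, so gains and losses are treated
symmetrically. Two search modes share this contract:

* `exact` enumerates all O(n²) intervals (compiled code; the default and
  entirely adequate up to a few tens of thousands of probes per array);
* `fast` scans a multi-resolution family (all lengths up to 32, then a
  geometric grid with ratio 1.1) and refines the best candidate by an exact
  search in a window of ±(0.25·length + 4) probes around its boundaries.
  It exists for very dense arrays and is property-tested to agree with
  exact mode.

Two deliberate deviations from the vendor tool, whose internals are not
public, are worth stating. First, the score uses a single per-array sigma
from the DLRS estimator rather than a proprietary per-probe error model;
this is reproducible from the data alone. Second, the **fuzzy-zero
correction** is implemented as an explicit post-hoc filter
(`fuzzy_zero_filter()`): each segment's quality is recomputed as
`|mean| / sqrt(sigma²/n + nu²)` and segments falling below the detection
threshold are dropped. The `nu²` term caps the precision a long segment can
claim: with `nu = 0` the filter is the identity on emitted segments, and as
n grows the quality saturates at |mean|/nu, so long, low-amplitude calls —
the typical baseline artifacts — are penalized most. The cohort default for
`nu` is the MAD of the per-array centralization offsets, the natural scale
of residual baseline uncertainty.

Reporting filters mirror the study conventions exactly: calls need at least
3 probes and |mean log2| ≥ 0.25 (both inclusive), and are classed
amplification/deletion when |mean log2| ≥ 0.8, else gain/loss.

## Cross-sample statistics and region algebra

**Common aberrations** (`detect_common()`). At each probe the observed
carrier count K is referred to a Poisson-binomial null in which sample s
covers any probe with probability g_s, its genome-wide aberrant fraction in
that direction (`genome_context()`). This is the "context correction":
globally rearranged or noisy samples contribute weaker evidence at any one
locus. The tail probability P(K' ≥ K) is computed exactly by dynamic
programming. Runs of probes with p < 0.05 become candidates; a sample is a
member only if one of its calls has reciprocal overlap ≥ 0.9 with the
candidate, and at least two members are required. No multiple-testing
correction is applied across probes by default (raw p < 0.05 is the study
convention); a Benjamini–Hochberg option is exposed behind the `adjust`
flag. The vendor's own context null is undocumented; only the thresholds
(0.05, 0.9) are taken from the study.

**CNARs** (`build_cnar()`). Same-direction calls are linked when reciprocal
overlap — min(|A∩B|/|A|, |A∩B|/|B|) — is *strictly* greater than 0.9
("more than 90 percent"), and each transitive-closure component with ≥ 2
distinct samples becomes a CNAR spanning the union hull of its members.
Transitive closure is a design choice: the source convention does not define
multi-segment grouping, and closure is the only order-independent option.

**MCRs** (`build_mcr()`). CNARs from different platforms (same chromosome
and direction) are grouped by any positive overlap; for groups observed on
all required platforms the MCR is the intersection of *all* member
segments — the region every supporting sample alters completely — and
groups with an empty intersection are dropped. Segment-wise intersection
(rather than probe-wise) is the implemented reading of "100 percent
overlapping"; the member table is kept on each region so the probe-wise
convention can be recomputed by a user who prefers it. MCR frequency counts
distinct supporting samples against the full cohort; a per-platform
breakdown is attached when platform sizes are supplied, since per-platform
frequencies naturally differ. Recurrence tables use a strict filter for the
"> 20%" convention and an inclusive one for "≥ 10%" (amplifications and
deletions). Genes fully contained in a region are reported separately from
genes merely overlapping it.

## MLPA, expression, and clinical statistics

MLPA peak ratios are population-normalized: probe height over the
within-sample mean of internal control probes, divided by the median of the
same quantity across the normal-tissue reference population. Ratios below
0.75 are deletions, above 1.25 amplifications, and the closed interval
[0.75, 1.25] is normal — the boundary values are assigned to "normal"
because the abnormal classes are defined by strict inequalities. The vendor
software's exact normalization scheme is not public; the control-probe/
median construction here is a documented stand-in with the right
invariances (it is exactly invariant to per-sample global scaling).

Expression fold change is ΔΔCt with efficiency 2:
`FC = 2^−[(Ct_g,T − Ct_ref,T) − (Ct_g,N − Ct_ref,N)]`. The one-sample
t-test runs on log2 FC (the natural symmetric scale), two-sided, and labels
a gene Up/Down at p < 0.05, "−" otherwise; strata with fewer than two
samples report a missing p. A sample "has the CNA" at a gene when a
same-direction call covers the gene's whole interval. Note the label
arithmetic this implies: for a truly decoupled gene both strata are
independent 5%-level tests, so even a perfect implementation reproduces the
"− / −" pattern in only about 0.95² ≈ 90% of cohorts — the residual 10% is
type-I error by construction, not a calibration defect.

Clinical statistics are the field-standard tests, delegated to base R and
`survival`: 2×2 chi-square with continuity correction when all expected
counts are ≥ 5, otherwise two-sided Fisher (mixed-type samples are excluded
from diffuse-vs-intestinal tables; the source is silent and n = 4 mixed
cases carry no power); Pearson correlation with Bonferroni correction by
multiplication with the number of tested genes, capped at 1; agglomerative
clustering with Euclidean distance and average linkage (unspecified in the
source; both exposed as arguments), rows pre-sorted by sample id so input
order cannot affect tie resolution; Kaplan–Meier curves with the 1-df
log-rank test. Loss-call size spectra between platform groups are compared
per size bin (1–5, 5–10, 10–50, 50–100, ≥ 100 kb) with the same
chi-square/Fisher switch.

## The synthetic cohort generator

`simulate_cohort()` emulates the study's data structure at desk scale:

* **Genome**: 3 autosomes × 10 Mb. Sex chromosomes are excluded to avoid
  ploidy bookkeeping the downstream analyses never use.
* **Platforms**: 10,000 / 5,000 / 1,500 probes (`default_designs()`),
  preserving the dense/medium/sparse structure of a 400K/244K/custom-60K
  design at 1/100 of genome scale; sample arms default to 30/10/48.
* **Cohort composition**: 43 diffuse / 41 intestinal / 4 mixed in 88,
  assigned exactly and permuted so platform arms are not type-confounded.
* **Aberrations** (`default_aberration_catalog()`): ten events. Gains are
  longer and more prevalent in intestinal-type samples; losses are shorter
  and type-neutral; one amplification (+1.3) and one deletion (−1.2) at
  ~12–15% prevalence. Two losses (12 and 20 kb) sit below the sparse
  platforms' 3-probe resolution on purpose — they reproduce the
  small-loss discordance between dense and sparse arrays that motivates
  the size-stratified comparison. A consequence worth knowing: with only
  10 samples on the medium arm, amplification/deletion MCRs (which need
  ≥ 2 supporting samples on *every* platform) are frequently absent at the
  default prevalences; the amplification/deletion table is exercised with
  constructed calls in the test suite instead.
* **Signal model**: carried `true_log2` on covered probes (containment,
  so planted boundaries are exactly recoverable), plus a per-array offset
  N(0, 0.1) (what centralization removes), plus `curvature × f(intensity)`
  where f is a mean-zero quadratic in log10 of a lognormal channel
  intensity (what lowess removes; default coefficient 0.15), plus iid
  N(0, 0.15) probe noise. The study does not report per-platform noise
  levels, so these are free parameters chosen once at plausible
  magnitudes, not estimates of the original arrays.
* **Clinical covariates**: age N(60, 10) truncated at 26; survival
  exponential with 30-month median under uniform 6–84-month administrative
  censoring (≈ 60% events), matching the scale of gastric-cancer follow-up.

What the generator does *not* model: tumor purity and subclonality (planted
amplitudes are clean multiples), replicate probes, dye-swap structure,
wavy-genome artifacts, and correlated noise. Recovery results on synthetic
cohorts are therefore upper bounds on real-array performance; the filters
and statistics, however, are exercised under exactly the rules they would
apply to real data.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open (BED-compatible) throughout. Segment
boundaries always coincide with probe boundaries. Score ties in detection
break leftmost-then-shortest; density-mode ties in centralization break
toward zero with a warning; a constant profile centralizes to zero with a
warning; a constant intensity covariate makes lowess an error (or identity,
by flag); zero-variance vectors make correlations an error naming the
offending vector, and make the one-sample t-test report p = 0 with the
sign's label (warning) or p = 1 for the all-zero case. The Poisson-binomial
DP is exact, so common-aberration p-values need no asymptotics at cohort
sizes in the tens.

## Problem sizes used in the checks

The test suite and the acceptance script run the full stack at 88 samples ×
(10,000 + 5,000 + 1,500) probes, recovery sweeps at 20 samples × 10,000
probes with noise 0.15 against events of ≥ 10 probes and |log2| ≥ 0.58, a
200-replicate null calibration of the common-aberration statistic at 15
samples × 1,000 probes, 500 randomized region-algebra instances against a
brute-force oracle, and 100 seeded expression cohorts of 26 samples. These
sizes were chosen so the whole suite runs on a laptop in a few minutes
while leaving every statistical check enough replicates to be meaningful.
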