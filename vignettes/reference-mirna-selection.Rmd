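---
title: "Selecting stable reference miRNAs for circulating-miRNA qPCR panels"
author: "mirnorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference miRNAs for circulating-miRNA qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnorm)
```

## The problem

Circulating miRNAs measured by qPCR in serum or plasma have no validated
universal housekeeping control: the small RNAs used for cellular samples
(RNU6, SNORDs) are unstable or undetectable in serum, and popular ad-hoc
choices such as miR-16 are confounded by hemolysis. At the same time the
measured threshold cycles (Ct) carry large nonbiological variability —
extraction yield, input amount, enzyme efficiency and the inter-individual
total miRNA concentration all act multiplicatively on every detector of a
sample. A defensible normalization therefore has to *discover* its reference
miRNAs from the data of each study, demonstrate their stability with more
than one criterion, and validate the choice independently.

`mirnorm` implements that workflow end to end: relative quantification
against a spike-in, quality control and detection filtering, imputation,
three complementary stability scores combined into a single summarized
stability score (SSS), reference selection under a one-per-family rule,
normalization-factor construction, and evaluation by CV-reduction curves and
PCA. A simulator with known ground truth makes every step testable without
external data.

## Relative quantities and normalization factors

With `Ct` the threshold cycle and an exogenous spike-in added to the lysis
buffer at fixed concentration, relative quantities are

$$\mathrm{RQ}_{ij} = 2^{-\Delta Ct_{ij}}, \qquad
  \Delta Ct_{ij} = Ct_{ij} - Ct_{\mathrm{spike},j},$$

which assumes amplification efficiency 2 for all assays. When two platforms
share no spike-in, the package instead references all detectors to the
highest-expressed one: the detector with the lowest arithmetic-mean Ct among
those observed in every sample (`compute_rq_min_ct()`). Because every
stability score below is invariant to per-sample rescaling, the choice of a
single-detector reference does not change any ranking; it only fixes the
scale. The per-panel (rather than per-sample) minimum is a deliberate
choice: a single reference detector keeps RQs comparable across samples,
whereas a per-sample minimum would switch references between samples.

The normalization factor of sample $j$ is the geometric mean of the $k$
selected references' RQs, and normalized relative quantities are
$\mathrm{NRQ}_{ij} = \mathrm{RQ}_{ij}/\mathrm{NF}_j$. By construction the
per-sample geometric mean of the references' NRQ is exactly 1, which the
test suite asserts to $10^{-12}$. Global alternatives (arithmetic mean,
geometric mean, median of all expressed detectors per sample) are available
through `normalize_global()`, and the spike-in stage and the endogenous NF
stage compose multiplicatively — they are computed and reported separately.

## Quality control, filtering and imputation

* **Censoring** (`censor_ct()`): observed wells with Ct strictly above the
  platform's reliability threshold (default 35 cycles) become missing with
  reason `above_threshold`. The inequality is strict, so a well at exactly
  35.0 is kept.
* **Low-Ct flagging** (`flag_low_ct_outliers()`): non-exponential
  amplification artefacts cross the threshold early and produce implausibly
  low Ct values that would corrupt sums and means of RQs. Wells below the
  floor (default 10 cycles; the rule matters more than the exact number)
  are flagged; `exclude_cells()` lets the analyst remove wells by hand.
  Flagging runs before the detection filter, so an artefactual well never
  counts as "detected".
* **Detection filter** (`filter_detection()`): a candidate normalizer must
  be detectable in *every* biological group, so a detector is kept only if
  it is present in at least `ceiling(fraction * n_g)` samples of each group
  (default fraction 2/3; `ceiling` because the rule is a lower bound).
* **Imputation** (`impute_knn()`): residual missing wells are imputed on
  the log2 scale, where qPCR noise is approximately additive and Euclidean
  distances are physically meaningful (cycles). For each missing well the
  `k` nearest detectors (default 10, capped at $m-1$) by Euclidean distance
  over jointly observed samples contribute a 1/distance-weighted mean;
  zero-distance neighbours receive equal weights among themselves.
* **Pseudo-detectors** (`add_pseudo_detectors()`): the per-sample
  arithmetic mean, geometric mean and median of the real detectors are
  appended as candidates. They compete in the ranking — central tendencies
  are known to be strong normalizers — but are never selectable as
  references and never contribute to column totals.

## The three stability scores

**geNorm-style stepwise M** (`genorm()`). The pairwise variation of
detectors $j,k$ is $V_{jk} = \mathrm{sd}\left(\log_2 (\mathrm{RQ}_j /
\mathrm{RQ}_k)\right)$ across samples (sample SD, $n-1$), and $M_j$ is the
mean of $V_{jk}$ over partners. The least stable detector (highest $M$,
ties resolved toward the lexicographically larger id) is removed and the
procedure repeats until two detectors remain. The score entering the SSS is
each detector's $M$ in the round of its elimination (the canonical stepwise
output); the single-pass full-set $M$ is kept alongside
(`genorm_variant = "fullset"`) because published rankings do not always say
which variant they used. `genorm_pairwise_v()` provides the usual
$V(n, n+1)$ series for choosing how many references to take — the number
itself is the analyst's decision (default 3 in `run_pipeline()`).

**Model-based variance decomposition** (`normfinder()`). Per group the
log2 data follow $y_{igj} = \alpha_{ig} + \beta_{gj} + \varepsilon_{igj}$;
the sample effect $\beta_{gj}$ absorbs per-sample scaling. The
detector-wise intragroup variance is estimated from two-way centred
residuals with a correction for the noise the other detectors contribute,
and truncated at zero. With several groups, the detector's group-mean
deviation from the panel average is shrunk by its signal-to-noise ratio and
combined with the posterior spread into a single stability value $\rho_i$
(lower is better): a detector is penalized both for intragroup noise and
for systematic intergroup shifts. With one group, $\rho_i$ reduces to the
estimated intragroup SD.

Two numerical notes. The zero-truncation makes the variance estimate
non-negative but slightly positive-biased wherever the true variance sits
far below the panel mean at small $n$ — the Monte-Carlo check in the test
suite therefore uses true variances spanning a 2.5-fold range
($\sigma^2 = 0.2 \dots 0.5$, $I = 10$, $n = 8$, 2000 replicates), where the
truncation is rare and the mean estimate reflects the moment estimator
itself; the estimator is exactly unbiased before truncation. Second, when a
panel contains a block of co-shifted (differentially expressed) detectors,
their shared shift leaks into the panel average, so even perfectly stable
detectors receive a small intergroup penalty; this is a property of the
model, not of the implementation.

**CV score** (`cv_score()`). Each sample's total RQ over real detectors is
a surrogate of its total miRNA amount; the share matrix
$X_{ij} = \mathrm{RQ}_{ij}/\sum_{i \in \mathrm{real}} \mathrm{RQ}_{ij}$
removes input differences and $\mathrm{CV}_i = \mathrm{sd}(X_{i\ast}) /
\mathrm{mean}(X_{i\ast})$ measures how constant the detector's share is.

All three scores are invariant to multiplying any sample column by a
positive factor (ratios cancel it; the model's sample effect absorbs it;
shares are scale-free). The test suite asserts this to $10^{-8}$ over
random matrices with factors drawn from $[0.1, 10]$.

## The summarized stability score

$$\mathrm{SSS}_i = \sqrt{M_i^2 + \rho_i^2 + \mathrm{CV}_i^2}$$

— the distance from the origin in score space, ranked ascending with ties
broken by detector id. The raw scores are combined without standardization
by default, matching the plain distance formula; because the three scores
live on different natural scales, `rescale = TRUE` offers a transparent
min-max variant. `select_references()` walks the ranking, skipping
pseudo-detectors and any miRNA whose family is already represented (family
members share seed sequences and possibly regulation), until `k` references
are collected.

For cross-platform studies, `combine_platforms()` restricts to the real
detectors detected on all platforms, min-max rescales each platform's SSS
to $[0,1]$ to make them commensurable (no formula for the combination is
canonical; this one is simple and monotone), and averages.
Pseudo-detectors are excluded there: they are per-platform constructs, not
shared assays.

## Evaluation

`cv_per_detector()` computes linear-scale CVs; `cv_reduction_summary()`
compares their empirical cumulative distributions across normalization
schemes on a shared 100-point grid spanning the pooled CV range — a grid
makes the usual visual "left-shifted curve" comparison testable, and a
scheme *dominates* raw when its ECDF is at least raw's at every grid point.

`autoscale()` standardizes each detector's log10 profile to mean 0, SD 1
(constant rows are dropped with a warning), and `pca_detectors()` runs a
PCA with detectors as observations via SVD of the column-centred matrix.
Signs are fixed deterministically (each loading's largest-magnitude entry
is non-negative) so that repeated runs and platforms agree. On autoscaled
data PC1 vs PC2 is the informative view; on unscaled data PC1 mostly
encodes abundance, so PC2 vs PC3 are used. `stability_separation()`
operationalizes the qualitative "stable detectors cluster at the narrow end
of the funnel" as the ratio of mean centroid distances of a top set versus
a bottom set; below 1 means the top set clusters more tightly. No numeric
criterion for funnel-ness is standard; this ratio is this package's
operationalization.

## The simulator and what passing tests mean

`simulate_ct()` draws, on the Ct scale,
$Ct_{ij} = b_i - a_{ij} - s_j$ with per-detector baselines
$b_i \sim U(20, 32)$ cycles, class-specific log2 abundance noise $a_{ij}$,
and per-sample scaling $s_j \sim N(0, 1)$ shared by all detectors of a
sample. The spike-in (baseline 22 cycles, i.e. an abundant
fixed-concentration spike) is modelled as added to the lysis buffer before
extraction, so it is co-extracted and receives the same $s_j$ plus its own
small technical noise (SD 0.05); spike referencing therefore removes $s_j$
by design. Wells above 35 cycles are censored to `undetermined`. Default
class structure: 5 stable detectors (SD 0.05), 15 variable (SD 0.5), 10
differential (SD 0.5 plus a log2 shift of 1.0 in the last of 2 groups of 8
samples). The differential class uses the variable-class noise SD — a
disease-associated serum miRNA is inter-individually variable, not
reference-grade — plus the shift; only the stable class is reference-like.
All draws flow from a single seed.

The generator emulates multiplicative technical scaling, censoring,
class-structured biology and a co-extracted spike. It does **not** emulate
hemolysis contamination, batch structure, amplification-efficiency
differences between assays, or a biological total-miRNA-concentration
component that a spike cannot correct. Consequently, passing tests show
that the algorithms recover designed stability structure under realistic
noise magnitudes — not that any particular miRNA is a good normalizer in
real serum.

On this design the test suite verifies (seeds 1–20, whole pipeline): the
mean recovery of the 5 designed-stable detectors in the SSS top-10 is
5 of 5, and reference-based normalization reduces the CV of most detectors.
One caveat the simulation exposes: the 10 differential detectors share one
shift direction, so after autoscaling they are mutually correlated
($r \approx 0.5$) and form a coherent PCA cluster of similar tightness to
the stable cluster. When the separation statistic is computed between the
SSS top-10 and the SSS bottom-10 — the bottom being mostly that coherent
differential block — the ratio hovers around 1 (below 1 in about half the
seeds). Computed between the *designed* stable and variable classes it is
below 1 in every seed the suite examines, typically by a wide margin. The
lesson for real data:
a tight cluster away from the stable end of the funnel is a signature of
co-regulated (e.g. disease-driven) miRNAs, not of noise, and the separation
statistic should be read together with the score ranking.

## Numerical choices

* Log base 2 throughout the scores (Ct is a base-2 scale); log base 10 for
  autoscaling and PCA, matching common practice for expression plots.
* Sample SDs use the $n-1$ denominator everywhere.
* geNorm pairwise variances are computed from the covariance of log
  profiles ($\mathrm{Var}(y_a - y_b) = C_{aa} + C_{bb} - 2C_{ab}$), with
  tiny negative values clamped to zero before the square root; tests check
  agreement with direct SD computation to $10^{-10}$.
* Ties: geNorm elimination removes the lexicographically larger id first;
  SSS ranks and the min-Ct reference resolve ties toward the smaller id.
* Variance estimates are truncated at zero (conventional moment-estimator
  fix); shrinkage weights with zero denominators are defined as zero.
* Observed cells are never altered by imputation (bit-identical
  pass-through); Ct values are written with 17 significant digits so file
  round trips are bit-exact.
* Test and acceptance problem sizes — 50 random matrices up to 10×12 for
  the geNorm oracle, 20 matrices for invariance, 2000 Monte-Carlo
  replicates at $I=10$, $n=8$ for the variance estimator, 20 simulated
  panels of 30 detectors × 16 samples for recovery — were chosen as the
  smallest designs that make the checked properties statistically
  unambiguous.

## Known limitations

* Efficiency is assumed to be exactly 2 for every assay; no
  efficiency-corrected NRQ model is provided.
* Batch-effect correction is out of scope; the package assumes batches are
  handled by design (or upstream), as is advisable when hunting for
  normalizers.
* The min-Ct reference uses the per-panel mean-Ct minimum; if the intended
  behaviour is a per-sample minimum, rankings are unaffected (scale
  invariance) but RQ scales differ.
* Replicate wells must be merged before import (duplicate detector ids are
  rejected); merging spike replicates on the Ct scale is supported via a
  multi-id `spike_id`.
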