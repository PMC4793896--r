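# mirnorm

Data-driven selection of stable reference miRNAs — and normalization — for
circulating-miRNA qPCR panels.

Serum and plasma miRNA panels have no validated universal housekeeping
control: the small RNAs used for cellular qPCR are unstable or undetectable
in serum, and ad-hoc favourites (miR-16) are confounded by hemolysis.
`mirnorm` is for researchers who profile circulating miRNAs by qPCR and need
to *discover* study-specific endogenous controls from their own data,
demonstrate the stability of those controls with more than one criterion,
and quantify how much nonbiological variability their normalization removes.

## What it computes

Starting from a wide Ct table (detectors × samples) and a sample/group
annotation:

1. **Relative quantities** against an exogenous spike-in,
   `RQ_ij = 2^-(Ct_ij − Ct_spike,j)`, or against the highest-expressed
   detector (minimum mean Ct) when platforms share no spike.
2. **Quality control**: censoring of `Ct > 35`, flagging of implausibly low
   Ct amplification artefacts, per-group detection filtering (≥ 2/3 of
   samples in *every* group), k-nearest-neighbour imputation on the log2
   scale, and appended central-tendency pseudo-detectors.
3. **Three stability scores** per candidate:
   - geNorm-style stepwise `M` — mean SD of pairwise log2 expression ratios,
     with iterative elimination of the least stable candidate;
   - a model-based stability value `ρ` from an intra/intergroup variance
     decomposition of `y = log2(RQ)` (sample effects absorb per-sample
     scaling; group shifts are shrunken and penalized);
   - a CV score — the coefficient of variation of each detector's share of
     the per-sample total RQ.
4. **The summarized stability score**
   `SSS = sqrt(M² + ρ² + CV²)`, ranked ascending; reference selection takes
   one miRNA per family, skipping pseudo-detectors.
5. **Normalization**: per-sample factors `NF_j` as the geometric mean of
   the selected references (or a global central tendency), and
   `NRQ_ij = RQ_ij / NF_j`.
6. **Evaluation**: per-detector CV cumulative distributions across
   normalization schemes, autoscaled-PCA validation of the ranking, and a
   cluster-tightness separation statistic; cross-platform score
   combination with rescaled means.

A synthetic serum-panel simulator with known ground truth
(`simulate_ct()`) exercises the whole pipeline without external data.

## Worked example

```r
library(mirnorm)

sim <- simulate_ct(sim_config(), seed = 42)   # 30 miRNAs + spike, 2 x 8 samples
ct  <- censor_ct(sim$ct, threshold = 35)
rq  <- compute_rq_spike(ct, spike_id = "spike_in") |>
  filter_detection(sim$annotation, fraction = 2/3) |>
  impute_knn(k = 10) |>
  add_pseudo_detectors()

tab <- stability_scores(rq, sim$annotation)
scores <- as.data.frame(tab[, c("detector", "genorm_m", "normfinder_rho",
                                "cv_score", "sss", "rank")])
print(head(scores, 6), digits = 3)
#>         detector genorm_m normfinder_rho cv_score   sss rank
#> 1 pseudo_geomean   0.2052        0.00147    0.132 0.244    1
#> 2  mir-stable-05   0.0590        0.17113    0.209 0.276    2
#> 3  mir-stable-04   0.0686        0.17115    0.212 0.281    3
#> 4  mir-stable-03   0.0408        0.19165    0.224 0.297    4
#> 5  mir-stable-02   0.0408        0.19984    0.230 0.307    5
#> 6  mir-stable-01   0.0505        0.21432    0.233 0.321    6
```

The five designed-stable miRNAs occupy the top real-detector ranks; the
geometric-mean pseudo-detector ranks first overall, as central tendencies
usually do, but is not selectable as a reference:

```r
refs <- select_references(tab, k = 3)
refs
#> [1] "mir-stable-05" "mir-stable-04" "mir-stable-03"

nr  <- normalize_by_references(rq, refs)
red <- cv_reduction_summary(rq, list(references = nr))
print(as.data.frame(red$summary), digits = 3)
#>       scheme median_cv fraction_reduced dominates_raw
#> 1        raw     0.362            0.000          TRUE
#> 2 references     0.362            0.758         FALSE
```

Here 76% of detectors have a lower CV after reference normalization; the
median barely moves because the spike-in referencing already removed the
per-sample scaling in this simulation, so the endogenous references mostly
polish residual noise. `autoplot(red)` draws the ECDF curves,
`pca_detectors(rq) |> autoplot(highlight = ...)` the detector PCA, and
`run_pipeline()` executes all of the above from a single YAML config and
writes TSV tables plus a JSON run report. A thin CLI (`exec/mirnorm`) wraps
`simulate`, `rank`, `normalize`, `evaluate` and `run`.

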