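---
title: "Quantifying neurovascular coupling from CBF and functional connectomes"
author: "nvcoupler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neurovascular coupling from CBF and functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoupler)
```

## The problem

Neurovascular coupling (NVC) is the physiological matching of regional
cerebral blood flow (CBF) to local neural demand. In populations at risk of
vascular cognitive impairment — the motivating case is end-stage renal
disease (ESRD) patients on maintenance hemodialysis — this matching can
degrade: perfusion rises or falls without a corresponding change in the
region's functional role, or connectivity changes without perfusion
following. `nvcoupler` quantifies this from two routinely acquired
modalities:

* **regional CBF** (mL/100 g/min), e.g. from arterial spin labeling,
  averaged over the 90 AAL atlas regions, and
* **resting-state BOLD time series** per region, from which a functional
  connectome is built.

Two families of NVC biomarkers are computed per subject:

1. **Global coupling coefficients** — the Spearman correlation, across the
   90 regions, between the CBF vector and a nodal topology vector (degree
   centrality DC, nodal efficiency Ne, betweenness centrality BC). A healthy
   brain shows clearly positive coupling (hubs are perfused more); a
   decoupled brain shows a weaker correlation.
2. **Regional coupling ratios** — CBF divided by the nodal metric,
   per region: "blood supply per unit of connectivity". A regional ratio can
   shift because CBF changed, because topology changed, or both; the
   package's *driving classification* separates these cases.

## Network construction and nodal metrics

Per subject, the timepoints-by-regions matrix is correlated (Pearson),
Fisher z-transformed, and binarized at every edge density of a sparsity
sweep (default 0.10 to 0.50 in steps of 0.01, 41 thresholds). Exactly
`round(s * N(N-1)/2)` edges are kept at density `s` — the strongest signed
z values, with ties broken deterministically by ascending region-index pair
so results are platform-independent. Ranking on signed z (not `|z|`)
reflects the hypothesis under study, which concerns dense *positive*
connectivity; `absolute = TRUE` switches to magnitude ranking for
sensitivity analyses. Because atanh is monotone, binarizing r or z yields
identical networks; the transform is kept for interoperability with
z-matrix workflows.

At each threshold three nodal metrics are computed on the full node set
(isolated nodes keep value 0, so vectors always have length N):

* `DC_i`: number of incident edges;
* `Ne_i = mean_{j != i} 1/d(i,j)` with unreachable pairs contributing 0;
* `BC_i`: unnormalized undirected betweenness (Brandes counts).

Each node's 41-point curve is integrated over the sweep by the trapezoidal
rule (a rectangle-sum option exists), giving threshold-independent AUC
scalars. All downstream comparisons are rank-based or linear in these
scalars, so the integration rule and the BC normalization convention do not
affect group inference; they are documented, not fitted. Small-world
verification (`smallWorldness()`) compares clustering and path length
against degree-preserving edge-swap references (default 100, with
`10 |E|` swap attempts each); an Erdős–Rényi null would not preserve the
degree sequence and is deliberately not used.

## Statistics

Test routing is fixed by design, not by normality screening: Mann–Whitney U
(normal approximation with mid-ranks, tie-corrected variance and continuity
correction, reported as a signed z) for CBF and all NVC indices; pooled
Student t for the nodal AUCs and demographics; Pearson chi-square without
continuity correction for the sex contingency. FDR correction
(Benjamini–Hochberg step-up; Benjamini–Yekutieli available) is applied
across the 90 regions *within* each index family — CBF is one family, each
nodal metric one, each ratio one — matching how per-parameter tables are
corrected in practice. Cognition correlations (ratio vs MoCA within
patients) are Spearman, reported uncorrected, with a partial variant that
rank-transforms all variables, residualizes on hemoglobin and hematocrit
ranks, and correlates the residuals (t reference with `n - 2 - k` degrees
of freedom). Constant covariates are dropped as no-op adjustments;
genuinely collinear covariates are an error.

A region's ratio is set to missing when its AUC denominator falls below
`1e-9` times the column maximum (near-isolated nodes at an aggressive
sweep); regions missing in more than 20% of subjects are excluded from that
family's tests with a logged notice.

## Driving classification

Among regions with a significant ratio change, the four categories are
determined by the two boolean drivers: CBF-significant and
nodal-significant (union over DC/Ne/BC by default; per-metric masks can be
supplied). `CBF_only` regions suggest perfusion changes preceding
functional change; `NODE_only` regions suggest connectivity loss with
preserved perfusion; `BOTH` combines them; `RATIO_only` regions are where
the ratio adds sensitivity beyond either marginal index. `overlapCounts()`
reports the full seven-cell Venn decomposition behind the overlap diagram.

## The synthetic cohort generator

No clinical dataset ships with the package; the generator is first-class,
tested code that emulates the statistical structure the analysis assumes,
with known ground truth for recovery testing.

**Covariance.** Regions are partitioned into contiguous modules
(`withinModuleCorr` = 0.30 inside, `betweenModuleCorr` = 0.05 across).
Hub structure is added as a rank-one shared factor `g g'` (diagonal reset
to 1): every region carries a graded loading
`baseLoading + loadingGradient * (i-1)/(N-1)` (0.15–0.40) and hub regions
carry `hubLoading` = 0.55. The factor form keeps the matrix positive
definite by construction — additively boosting hub rows, the obvious
alternative, loses positive definiteness already at ~10 hubs — and gives
every region a distinct expected connectivity mass ("hubness"), which a
rank correlation across regions needs. Both group covariances are
Cholesky-checked at configuration time; failures name the offending
parameters.

**Time series.** `nTimepoints` = 230 i.i.d. multivariate normal draws per
subject. The pipeline consumes correlations, not spectra, so temporal
autocorrelation is off by default; an AR(1) option (`ar1`) exists for
sensitivity studies, with innovations rescaled to unit marginal variance.

**CBF.** `CBF_i = 60 + slope_group * hubness_i + N(0, 10)` mL/100 g/min,
where hubness is the standardized off-diagonal mass of the *control*
covariance in both groups: vascular supply follows the premorbid
architecture, and the patient deficit is expressed solely through the
reduced slope. (Deriving patient hubness from the attenuated patient
covariance would leak a CBF decrease into the disconnection regions and
blur the injected effect categories.) Negative draws are resampled, not
clipped, so CBF is strictly positive without a point mass. The control
slope default of 7.5 mL/100 g/min per SD of hubness was chosen once so that
the realized per-subject coupling coefficients land near the mid-0.4s
observed in healthy adults; the patient slope defaults to 50% of the
control slope. Patients additionally receive `cbfOffset` = 22 mL/100 g/min
in the hyperperfusion regions (+37% of baseline, central in the 25–60%
elevations reported for significantly hyperperfused regions in this
population), and their covariance entries incident to the disconnection
regions are multiplied by `disconnectionAttenuation` = 0.5.

**Phenotype.** MoCA is a truncated normal — patients from
N(22.6, 3.6²) truncated below 26, controls from N(28.1, 2.2²) truncated to
[26, 30] — kept continuous because integer rounding would break the strict
inclusion-criterion truncation. Patient hemoglobin N(95.36, 4.12²) g/L and
hematocrit N(27.17, 1.79²)% reflect the anemic profile of a dialysis
population; controls' labs are left missing, as the covariate-adjusted
correlations are computed within patients only. Ages are truncated to
30–65. All draws use inverse-CDF sampling, so one seed determines the
cohort bit-for-bit.

**Default effect placement** (90 regions) mirrors the anatomy implicated in
hemodialysis cohorts: hubs in default-mode/limbic territory (SFGmed, PCG,
HIP, ANG, PCUN), hyperperfusion in DCG, PHG.R, LING and SPG, disconnection
in MFG, HES.L, TPOsup.L and PHG.R — with PHG.R carrying both effects, and
the disconnection set kept clear of the hubs so NODE_only ground truth is
not confounded by the slope-driven CBF change at hub regions so every driving
category has injected truth. For other region counts,
`defaultRegionSets()` places the sets deterministically in thirds of the
index range with one shared hyperperfusion/disconnection region.

**What the generator does not emulate:** raw BOLD volumes, head motion,
physiological noise, scanner drift, session (dialysis-cycle) effects, and
spatially realistic voxel-level structure. Passing recovery tests therefore
demonstrates that the *pipeline* detects effects of the modeled kind at the
modeled strength — not that any particular clinical effect size will be
detected in real data.

## Numerical and design choices

* Edge-count rounding uses `round()` (round-half-even).
* Degenerate inputs: constant time-series columns are an error naming the
  region; `|r| = 1` correlations are clamped to `1 - 1e-7` with a warning
  before atanh; all-tied Mann–Whitney samples return z = 0, p = 1.
* Mann–Whitney is implemented directly (base R exposes no signed-z form);
  it matches `wilcox.test`'s corrected p-values and exact enumeration of U
  in the tests. FDR uses `p.adjust`; graph algorithms use igraph; tests
  compare them against independent Floyd–Warshall / matrix-power oracles.
* Result tables are serialized at 17 significant digits and the pipeline
  manifest contains no timestamps, so identical configuration and seed
  reproduce byte-identical outputs.
* The calibration and recovery suites run on reduced problem sizes chosen
  as a package design point — null calibration on 20-region, 100-timepoint
  cohorts (the coupling statistic's null behaviour does not depend on the
  region count), recovery on the full 90-region parcellation with
  100-timepoint series and the degree-centrality path, where the injected
  effects live.

## A worked example

```{r example, eval = FALSE}
cfg <- cohortConfig(seed = 17)          # 45 patients / 40 controls, 90 x 230
res <- runPipeline(cfg, outDir = "nvc-results")
res$couplingTests                       # group medians, z, p per metric
table(res$driving$category)             # what drives the ratio changes
head(res$behavior)                      # ratio-MoCA correlations, adjusted
```

## Known limitations

* ROI-level inputs only: voxel-level preprocessing (registration,
  smoothing, nuisance regression) must happen upstream; the NIfTI on-ramp
  (`extractRoiMeans()`) only averages an already-aligned CBF volume over an
  atlas.
* Binary networks only; no weighted or dynamic connectivity variants.
* The normal-approximation Mann–Whitney p stays within 0.05 of the exact
  permutation p for untied samples once both groups have at least 3
  observations (verified by enumeration in the tests); it degrades below
  that and under heavy ties, where only the U statistic itself is exact. At
  the shipped group sizes (45/40) the approximation error is negligible.
* Whether published nodal AUC values integrate raw or normalized metrics is
  toolbox-dependent; both conventions are computable here (`rule`,
  normalization left to the caller), and all shipped comparisons are
  invariant to the choice.
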