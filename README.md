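# nvcoupler

Neurovascular coupling (NVC) analysis of functional brain networks in R.

Cognitive decline in vascular-risk populations — the motivating case is
end-stage renal disease patients on maintenance hemodialysis — can arise
from a mismatch between regional cerebral blood flow (CBF) and the brain's
functional architecture. `nvcoupler` measures that mismatch from two
ROI-level inputs per subject: a regional CBF vector (mL/100 g/min, e.g.
from arterial spin labeling averaged over the 90 AAL atlas regions) and a
resting-state BOLD time-series matrix (timepoints × regions).

**Core statistics.** Each subject's connectome is built by Pearson
correlation, Fisher z-transform, and binarization across a sparsity sweep
(densities 0.10–0.50, step 0.01). Per threshold, three nodal metrics are
computed — degree centrality (DC), nodal efficiency
(Ne_i = mean over j of 1/d(i,j)), and betweenness centrality (BC, Brandes
counts) — and integrated over the sweep into AUC scalars. The NVC
biomarkers are then

* the **global coupling coefficient** per subject and metric:
  Spearman's rho across the N = 90 regions between the CBF vector and the
  nodal AUC vector (rho_DC, rho_Ne, rho_BC), and
* the **regional coupling ratio** per region: CBF_i / AUC_i for each
  metric — blood supply per unit of connectivity.

Group inference uses Mann–Whitney U (signed z, tie-corrected, continuity
correction) for CBF and NVC indices, pooled Student t for nodal AUCs,
chi-square for sex, Benjamini–Hochberg FDR across the 90 regions within
each index family, and Spearman/partial-Spearman (adjusting hemoglobin and
hematocrit) for cognition correlations. Regions with a significant ratio
change are classified by what drives them: `CBF_only`, `NODE_only`,
`BOTH`, or `RATIO_only`.

A synthetic cohort generator (`cohortConfig()` / `generateCohort()`)
produces patient/control cohorts with modular hub-structured covariance,
CBF coupled to network hubness, and injected ground-truth effects
(reduced patient coupling slope, regional hyperperfusion, regional
disconnection), for power and type-I-error calibration of the whole
pipeline.

## Worked example

```r
library(nvcoupler)

cfg <- cohortConfig(nPatients = 45, nControls = 40, seed = 17)
res <- runPipeline(cfg, outDir = "nvc-results")

res$couplingTests
#>  metric median_patient q1_patient q3_patient median_control q1_control
#>      dc     0.17834447 0.13001605  0.2503612      0.4680081  0.4218563
#>      ne     0.19400749 0.12524180  0.2515290      0.4799440  0.4167222
#>      bc     0.09099889 0.02577273  0.1719965      0.2517759  0.2007408
#>  q3_control         z            p
#>   0.5381788 -7.875633 3.390211e-15
#>   0.5465325 -7.849220 4.186333e-15
#>   0.3504877 -6.863115 6.737503e-12

table(res$driving$category)
#>   CBF_only  NODE_only       BOTH RATIO_only
#>         19          6          3          2
```

The coupling table shows what the method is built to detect: patients'
median CBF–DC coupling (0.18) sits far below controls' (0.47), with
strongly negative Mann–Whitney z for all three metrics — the injected 50%
slope reduction. The driving table attributes the significant regional
ratio changes: the six hyperperfusion regions are among the `CBF_only`
rows (the rest of that category comes from slope-driven CBF shifts at
high-hubness regions), the disconnection regions appear as `NODE_only`,
and the region carrying both injected effects as `BOTH`.

Result files (`region_comparisons.tsv`, `coupling_coefficients.tsv`,
`coupling_group_tests.tsv`, `behavior_correlations.tsv`,
`driving_categories.tsv`, `overlap_counts.json`) plus a `manifest.json`
with the configuration hash are written to `outDir`; identical
configuration and seed reproduce them byte-for-byte.

See `vignettes/nvc-methods.Rmd` for the model, parameter defaults and
their rationale, numerical conventions, and limitations.

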