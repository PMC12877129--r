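# tet2traj

Pseudotime event ordering, trajectory projection, feedback detection, and
survival analysis for studies of TET2 cytoplasm–nucleus shuttling in
colorectal cancer — with a synthetic-data generator that makes every stage
testable against known ground truth.

## What it is for

TET2 demethylates DNA only in the nucleus. As colorectal tumor cells
progress (modeled by long-term colony culture and profiled with single-cell
RNA-seq), several transcriptional programs switch state: metabolism shifts
from oxidative phosphorylation to glycolysis, WNT targets and EMT markers
activate, and TET2 target genes switch on as TET2 relocates to the nucleus.
This package implements the quantitative backbone of such an analysis:

* **Event ordering.** Cells get a pseudotime t ∈ [0, 100] (PC1 of z-scored
  module genes, root-oriented, rank-transformed) and are split into 100
  equal-count groups. Each gene module's binned score s(t) is fit with a
  four-parameter logistic

  s(t) = base + amp / (1 + exp(−k (t − t50))),

  and the half-activation point t50 is the module's event time. Sorting
  event times gives the temporal order of progression events; bootstrap
  resampling attaches pairwise order support.
* **Trajectory projection.** External single-cell or bulk profiles are
  placed on the reference trajectory by correlating them with per-bin
  centroids; groups of samples (e.g. primary vs metastatic) are compared by
  a permutation Kolmogorov–Smirnov test on their assigned bins.
* **Negative-feedback detection.** Within the mid-trajectory window (bins
  36–75) the slope of the EMT score on the TET2-target score is compared
  between groups (conditions, or TET2-high vs TET2-low strata) with a
  label-permutation test; an attenuated slope in the high-TET2 group is the
  feedback signature.
* **Survival by TET2 localization.** Samples are classified by nuclear-TET2
  fraction into nucleus only (≥ 90%), nucleus major (50–90%), cytoplasm
  major (10–50%), and cytoplasm only (< 10%); Kaplan–Meier curves,
  restricted mean survival and the log-rank test compare the categories,
  and cross-tabulation against Duke's/TNM stage uses a chi-square test.
* **Synthetic data.** `simulate_cells()`, `simulate_bulk_cohort()` and
  `simulate_ihc_cohort()` generate negative-binomial single-cell counts
  along a latent progression with staggered sigmoid module programs
  (optional TET2→EMT/WNT feedback coupling), bulk samples as stage-linked
  cell averages, and survival cohorts whose hazard decreases with nuclear
  TET2 — all deterministic given a seed, with ground truth returned.

File formats: Matrix Market triplets (matrix.mtx + barcodes.tsv +
features.tsv, orientation auto-detected), GMT gene sets, CSV cohorts, JSON
configuration.

## Worked example

```r
library(tet2traj)

cfg <- default_config()     # 5 modules, midpoints 30/30/45/50/65
cfg$n_cells <- 1000
cfg$seed <- 42
sim <- simulate_cells(cfg)
res <- run_event_ordering(sim$matrix, sim$modules, n_bins = 100)
res$order
#> EventOrder: GLYCOLYSIS -> OXPHOS -> WNT_TARGETS -> EMT_MARKERS -> TET2_TARGETS
#>   event times: GLYCOLYSIS=31.2, OXPHOS=31.4, WNT_TARGETS=46.5, EMT_MARKERS=51.1, TET2_TARGETS=63.9
#>   ties: GLYCOLYSIS~OXPHOS
```

The two metabolic modules (true midpoint 30 for both) come out first and
tied, WNT precedes EMT, and the TET2 targets (true midpoint 65) come last —
the recovered event times sit within ~1.5 pseudotime units of the
generative truth.

```r
rec <- simulate_ihc_cohort(n_samples = 263, hazard_beta = 1.5,
                           censor_rate = 0.2, seed = 42)
table(rec$category)
#>    nucleus_only   nucleus_major cytoplasm_major  cytoplasm_only
#>              30             107             102              24
lr <- logrank_test(data.frame(time = rec$time, event = rec$event,
                              group = rec$category))
#> log-rank chi-square = 19.93, df = 3, p = 0.000175
```

With a protective nuclear-TET2 hazard (β = 1.5) the four localization
categories separate clearly in a 263-patient cohort.

See `vignettes/event-ordering.Rmd` for the model, the generator's
assumptions, and the reasoning behind the numerical choices.

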