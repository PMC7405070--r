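# claustrotype

Cell-type classification for mouse claustrum neurons from whole-cell
current-clamp recordings.

The claustrum contains at least eight electrophysiologically distinct cell
types — five projection-neuron subtypes (PN1–PN5) and three interneuron
subtypes (PV, SST, VIP) — that can be told apart from a family of 1-s
current steps alone. `claustrotype` reduces such a recording to the
canonical intrinsic property sets (38 properties at the current threshold
*ct* and 2×ct; 63 properties adding the maximal-firing level), and builds
two analyses on top:

* **Unsupervised taxonomy** — per-property Z-scores, hierarchical clustering
  (Pearson correlation distance with average linkage at the population
  stage; Euclidean/Ward within groups), silhouette-based selection of the
  cluster number over k = 2…9 (average width < 0.25 flags random
  structure), and t-SNE/LLE validation embeddings.
* **Supervised three-stage classifier** — standardize, PCA to ≥ 99%
  retained variance, single-hidden-layer softmax network (10 hidden units,
  L2 weight decay 0.001; a 10-fold-CV grid search is available via
  `tune = TRUE`). Stage 1 separates INs from PNs; conditional stages
  resolve PN1–PN5 or PV/SST/VIP; eight-way probabilities are
  branch × within-branch products.

A Q10 module corrects properties between recording temperatures
(Q₁₀ = (P₂/P₁)^(10/(T₂−T₁)), with IQR-fenced aggregation and a shipped
per-property coefficient table referenced to 24 °C), and a synthetic-data
module samples feature-table cohorts from the published per-subtype
distributions and simulates subtype-typical spiking traces (doublet firing
with ADP, delayed onset, fast spiking, irregular firing), so the whole
pipeline runs without any raw recordings. I/O covers episodic ABF v1 files,
a plain CSV sweep dialect, and feature-table CSVs using the canonical
printed property labels.

See `vignettes/claustrotype-methods.Rmd` for the property definitions, the
model assumptions, and what the synthetic cohorts do and do not emulate.

## Worked example

Train the three stages on synthetic cohorts and classify the one printed
single-cell property vector the package ships — the outlier VIP interneuron
whose action-potential waveform resembles a projection neuron:

```r
library(claustrotype)
library(dplyr)

pop  <- sample_cohort(cohort_counts("population"), set = 38, seed = 1)
pnin <- mutate(pop, label = ifelse(label %in% c("PV", "SST", "VIP"), "IN", "PN"))

cross_validate(pnin, seed = 1)
#> <ctype_cv> pooled 10-fold CV accuracy: 100.0%

clf <- fit_classifier(pnin,
                      sample_cohort(cohort_counts("pn"), 38, seed = 2),
                      sample_cohort(cohort_counts("in"), 63, seed = 3),
                      seed = 1)
predict(clf, outlier_vip_vector())[, c("cell_id", "p_PN", "p_PN5", "label")]
#> # A tibble: 1 × 4
#>   cell_id      p_PN p_PN5 label
#>   <chr>       <dbl> <dbl> <chr>
#> 1 outlier_VIP 1.000 0.995 PN5
```

The classifier places this genuine VIP interneuron among the projection
neurons, next to PN5 — the same anomaly its immunohistochemical
identification exposed. Simulated recordings run the extraction end to end:

```r
s <- simulate_sweepset("PV", seed = 7)
s
#> <sweepset> cell 'PV_sim7': 30 sweeps x 60000 samples @ 50 kHz
fx <- extract_features(s, 63)
round(unlist(fx[, c("Rm (MΩ)", "current threshold (ct: pA)",
                    "2xct: # AP", "ct: AP half-width (ms)")]), 2)
#>                    Rm (MΩ) current threshold (ct: pA)
#>                     156.95                     160.00
#>                 2xct: # AP     ct: AP half-width (ms)
#>                      59.00                       0.64
```

A fast-spiking PV cell: low input resistance, high current threshold, many
narrow spikes. `autoplot(s)` draws the sweep family; `qc_check()` applies
the recording exclusion rules; `correct_to_reference()` maps features
recorded at another bath temperature back to 24 °C.

A thin command-line front-end over the same functions is installed as
`exec/claustrotype` (subcommands `simulate`, `sample-cohort`, `cluster`,
`train`, `classify`, `q10-correct`).

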