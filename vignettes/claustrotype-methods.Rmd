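---
title: "Classifying claustrum neurons from intrinsic electrical properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying claustrum neurons from intrinsic electrical properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(claustrotype)
library(dplyr)
```

## The problem

The claustrum contains at least eight electrophysiologically distinct cell
types: five projection-neuron subtypes (PN1–PN5) and three interneuron
subtypes expressing parvalbumin (PV), somatostatin (SST) or vasoactive
intestinal peptide (VIP). These types can be told apart from whole-cell
current-clamp recordings alone — a family of 1-s current steps, sampled at
50 kHz — once the recording is reduced to a canonical set of intrinsic
electrical properties. claustrotype implements that reduction and the two
analyses built on it: an unsupervised taxonomy (hierarchical clustering with
silhouette-based model selection) and a supervised three-stage classifier.

## The property sets

Two canonical property sets are used, both fixed by `property_registry()`:

* the **38-property set** describes a cell at the current threshold (*ct*,
  the smallest current that elicits an action potential) and at twice that
  current (2×ct), plus cross-sweep adaptation measures and the
  afterdepolarization (ADP) descriptors;
* the **63-property set** adds a third stimulus level — the current evoking
  the maximal firing rate ("Max AP") — and waveform-ratio properties, and is
  used for interneuron work, where waveform and maximal-firing differences
  carry most of the signal.

Key definitions, all implemented in `detect_aps()`, `ap_waveform()`,
`ahp_features()`, `detect_adp()` and `train_statistics()`:

* **AP threshold**: first sample of a suprathreshold excursion where
  dV/dt > 10 mV/ms (central differences on the raw 50-kHz trace, with a 1-ms
  debounce so noise cannot re-trigger inside an upstroke). APs must overshoot
  0 mV to count.
* **Waveform**: amplitude (peak − threshold), half-width (between
  half-amplitude crossings, interpolated), maximum rise/decay of dV/dt, and
  their ratios. The decay window runs from the threshold crossing to the AHP
  trough, capped at +10 ms.
* **AHP**: trough between an AP's peak and the next AP's threshold (or
  window end), reported threshold-referenced; its latency is measured from
  the AP peak (the reference point is not fixed by convention; the peak is
  used here and can be audited in `ahp_features()`).
* **ADP**: after the first AP at *ct*, the trace is smoothed with a causal
  8-pole 50-Hz Bessel filter; an ADP is a local maximum followed by a local
  minimum of the smoothed slope. Because the causal filter delays the trace
  (about 10 ms at 50 kHz), turn points are mapped back by the filter's
  impulse-response centroid, and slope phases shorter than 4 ms are ignored
  — structure faster than that is not resolvable under a 50-Hz cutoff. The
  integrated amplitude is the mean positive residual above the straight line
  from the AHP trough to the post-ADP minimum.
* **Train statistics**: ISIs run peak-to-peak; adaptation is the first-pair
  instantaneous frequency minus the mean frequency of the last three APs.
  Three APs bound only two ISIs, so "last three" is read as the last three
  inter-AP frequencies when at least four ISIs exist, otherwise the last
  two; adaptation statistics require five APs, and anything unmeasurable is
  `NA`, never zero. Cv2 is `2|ΔISI|/(ISI₁+ISI₂)` averaged along the train.
  The SD of the first two ISIs is the sample SD (n−1 denominator) of the
  two values.
* **Passive properties**: membrane resistance is the slope of the V–I fit
  over subthreshold steps (mV/pA × 1000 = MΩ) and the resting potential is
  its zero-current intercept; steady state is the mean over the last fifth
  of the stimulus window.

Quality control (`qc_check()`) excludes recordings with access resistance
above 30 MΩ, Ra/Rm above 20%, resting potential above −50 mV or drifting by
more than 5 mV (the drift limit is this package's own numeric reading of
"unstable"), non-overshooting APs, and — for maximum-activity features only —
firing that does not saturate at the top two current steps. Voltages are used
as recorded; the ~−11.7 mV liquid-junction offset typical of K-gluconate
fills is *not* subtracted, matching the recording convention the property
tables assume.

## Unsupervised taxonomy

Features are Z-scored per property (constant properties are zeroed with a
warning; missing values are imputed at the population mean, i.e. Z = 0,
which keeps them neutral in every distance). The population stage clusters
all neurons on Pearson correlation distance (1 − r between cell profiles;
the sign of r is kept, so anti-correlated profiles are maximally distant)
with average linkage; subclustering within the PN or IN groups uses
Euclidean distance with Ward linkage (`ward.D2`, i.e. proper Ward on
distances). `silhouette_curve()` evaluates k = 2…9, computed on the same
distances used for clustering, with singleton clusters given width 0 and
ties in the argmax resolved toward the smallest k; an average width below
0.25 flags random structure. t-SNE (`tsne_embed()`) uses PCA initialization,
learning rate 200, at most 1000 iterations, and per-dataset
perplexity/exaggeration of 25/1 (all neurons), 8/7 (PN) and 7/7 (IN), with
exaggeration applied over the standard 250-iteration early phase.
`lle_embed()` is a standard locally linear embedding with
Tikhonov-regularized reconstruction weights and 14 (PN) or 13 (IN)
neighbours; the "modified" LLE variant's multi-weight construction is not
reproduced — with these sample sizes the standard embedding separates the
same structure, and it keeps the implementation auditable.

## The three-stage classifier

`fit_stage()` standardizes, reduces by PCA to the fewest components holding
at least 99% of the variance (the component count is data-driven, not fixed),
and trains a single-hidden-layer softmax network (`nnet`), 10 hidden units
and L2 weight decay 0.001 by default — the hyperparameters a 10-fold
cross-validated grid search (hidden 2/5/10/20 × decay 10⁻⁴/10⁻³/10⁻²,
`tune = TRUE`) selects on cohorts of this size. Stage 1 (IN vs PN) and the
PN-subtype stage use the 38-property set; the IN-subtype stage uses the
63-property set. `predict()` reports all eight type probabilities as
branch probability × within-branch probability, so they sum to one, and the
final label follows the argmax chain. Folds are stratified with at least
three cells per class enforced.

## Temperature correction

Each property's temperature coefficient is
Q₁₀ = (P₂/P₁)^(10/(T₂−T₁)); `aggregate_q10()` pools per-cell values after
discarding those outside [Q1 − 3·IQR, Q3 + 3·IQR] and reports the mean and
SEM of the survivors. The shipped table (`claustrum_q10_table()`) covers the
canonical properties, referenced to 24 °C. `correct_to_reference()` divides
by Q₁₀^(ΔT/10) on magnitudes with the sign restored — the exponential form
is undefined across sign changes, and coefficients for negative-valued
properties (AHP amplitudes, decay rates) are tabulated for their magnitudes.
Ratio-valued properties with extreme coefficients are corrected like any
other; pass a reduced table to exempt them. Properties without a coefficient
pass through with a warning, and missing values stay missing.

## What the synthetic data emulates

The package ships no recordings: `sample_cohort()` draws feature-table
cohorts from the published per-subtype distributions, and
`simulate_sweepset()` produces spiking traces so the extraction path itself
can be exercised.

**Cohort sampler.** PN subtypes are centred on the published medians with
scale 1.4826 × MAD; IN subtypes on the published means with scale
SEM × √n (n = 19 PV, 28 SST, 30 VIP). Strictly positive heavy-tailed
properties (input resistance, latencies, Cv2, ISI dispersion) are drawn
log-normally by moment matching, everything else normally, and draws are
clipped to physical ranges (probabilities to [0, 1], Cv2 to [0, 2], and so
on). Where a printed dispersion is zero the other printed dispersion (or 2%
of the centre) stands in, so every prototype has a positive scale.
Properties are drawn **independently** — the within-cell covariance
structure is not published, so none is invented. Independence makes classes
*more* separable to a supervised classifier than real data would be (every
property contributes independent evidence), which is why the classifier
checks are one-sided. It has the opposite effect on the correlation-distance
population clustering: with independent draws the PN1 profile is nearly
orthogonal to the other PN profiles, and the k = 2 cut attaches PN1 to the
IN side — in real recordings the within-cell correlations across properties
are what make that split clean. Passing classifier tests on these cohorts
therefore demonstrates the pipeline, not real-data performance.

Default cohort sizes follow the study proportions: 174 PNs and 152 INs
(19:28:30 PV:SST:VIP). Per-subtype PN counts are not published, so the 174
PNs are split evenly (35/35/35/35/34); the IN-subtype stage uses the
labeled-IN proportions scaled four-fold (76/112/120). The six 38-set
properties never tabulated per IN subtype (ADP descriptors and the
cross-sweep adaptation measures) inherit the IN-population distribution in
all three IN subtypes. The single outlier VIP interneuron's printed property
vector ships verbatim (`outlier_vip_vector()`).

**Trace simulator.** An adaptive integrate-and-fire model: leak integrator
with the subtype's resting level and input resistance; threshold placed at
95% of the subtype's current threshold; a fast spike-triggered adaptation
conductance reversing at the AHP trough, whose jump and decay constant are
derived in closed form from the subtype's initial instantaneous frequency
and ISI ratio (in the adaptation-dominated regime the ISI is approximately
τ_w·log((g* + b)/g*) with g* the conductance at which the shunted
equilibrium recrosses threshold); a slow adaptation current for late
adaptation; a depolarizing after-current producing doublet firing and the
ADP; a relaxing threshold offset for delayed-onset firing (PN5); a
refractory floor that saturates the f–I curve at the top of the ladder (the
interneuron max-activity criterion); and Ornstein–Uhlenbeck current noise
for irregular firing (VIP). Spikes are rendered as raised-cosine templates
whose rise/decay durations reproduce the subtype's rise and decay rates and
half-width, with amplitude decrement along the train. The simulator
reproduces the anchor properties (RMP, Rm, ct, AP counts) and the published
group orderings; it does not reproduce every marginal distribution, and its
noise can imitate an ADP-like wobble in the high-noise VIP preset — the
ADP *probability* contrasts between subtypes are therefore coarser than the
printed ones.

## Numerical choices and degenerate inputs

* Sweeps are re-ordered by current; ties in the 2×ct sweep choice go to the
  lower amplitude, ties in the max-activity sweep to the lowest amplitude.
* The Bessel filter is built from the analog Bessel poles (reverse Bessel
  polynomial roots, −3 dB normalized), pre-warped and bilinear-transformed
  into four cascaded biquads — an 8th-order transfer function at 50 Hz/50 kHz
  is numerically unusable in direct form.
* Cohorts, simulations, fold assignments and network initializations are all
  seed-controlled; the same seed reproduces results bit for bit.
* Problem sizes in the test-suite simulations (single cells per subtype,
  reduced ladders) were chosen so the whole suite exercises every path at
  interactive time scales; the accuracy checks use full-size cohorts
  (326/174/308 cells).

## Known limitations

* ABF support covers version-1 episodic files (int16/float32) with a
  recorded stimulus channel or a step epoch table; ABF2 files must be
  exported to ABF1 or the CSV sweep dialect.
* The published 38 and 63 property *marginals* constrain the cohort
  sampler, but nothing constrains the joint distribution; every result on
  synthetic cohorts inherits that caveat (see above).
* The trace simulator is phenomenological: it targets the anchor properties
  and firing phenotypes, not biophysical mechanism.
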