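---
title: "Hemispheric connectivity topology: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric connectivity topology: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemitopo)
```

# The problem

Focal brain lesions alter the function of regions far from the damage, and
how fast the lesion develops appears to shape how the surviving network
reorganizes. `hemitopo` implements a two-arm analysis of hemispheric
resting-state functional connectivity for two-group cohort designs — the
motivating case is slow-growing versus fast-growing glioma, analysed in the
hemisphere contralateral to the lesion, the only part of the brain that can
be treated as tumour-free across a heterogeneous cohort:

* **Arm A — multivariate pattern classification.** Can the group be predicted
  from the ROI-pair connectivity pattern alone? Kendall-tau feature ranking,
  a linear support vector machine under leave-one-out cross-validation
  (LOOCV), and a label-permutation null for the overall accuracy.
* **Arm B — weighted graph topology.** Which global network properties
  differ? Global and local efficiency normalized against rewired null
  networks, weighted modularity Q, and intra-/intermodular connectivity,
  all integrated over a range of proportional sparsity thresholds, with
  permutation group tests, FDR correction, and ANOVA adjusted for age and
  lesion diameter.

Both arms consume per-subject Fisher-z connectivity matrices built from
denoised ROI time series; a synthetic cohort generator with block-modular
correlation structure provides fully controlled inputs for calibration and
power analysis.

# From time series to connectivity

Each subject enters as a timepoints-by-ROI panel (45 ROIs for one hemisphere
in the reference design, 301 volumes at TR = 1.5 s). The chain is:

1. **Quality gate.** Temporal signal-to-noise ratio (mean/SD per ROI, on the
   raw series, averaged across ROIs). Subjects below the threshold (default
   45, the lower bound for resolving sub-0.5% signal fluctuations at this
   scan length) are excluded. The summary statistic (mean across ROIs) is a
   package choice; only the threshold is given by the field.
2. **Confound regression.** OLS residualization on an intercept plus any
   supplied nuisance columns (motion parameters, tissue signals, spike
   indicators — the package treats them uniformly as given regressors,
   since their extraction from images is upstream of this package).
3. **Detrend + band-pass.** Best-fit line removal, then an ideal FFT mask
   keeping 0.009–0.8 Hz. The mask is deterministic and parameter-free,
   which we prefer over IIR filters for reproducibility. At TR = 1.5 s the
   Nyquist frequency is 0.333 Hz, so the conventional 0.8 Hz upper edge is
   unreachable; the filter clamps to Nyquist (logged) and the step is
   effectively a drift-removing high-pass. A residual best-fit line is
   removed after masking so the no-trend postcondition holds exactly.
   Like every finite-window rectangular mask, the filter is ideal per DFT
   bin but not pointwise: in-band sinusoids keep their RMS amplitude to
   well under 1% while showing edge (Gibbs) deviations, and drift
   components slower than the 1/T frequency resolution (~0.0022 Hz at 301
   volumes) leave a few percent of incoherent leakage even though their
   coherent part is removed essentially completely.
4. **Correlation.** Pearson correlation of every ROI pair, Fisher
   transformed (`atanh`), zero diagonal; `|r|` at 1 is clamped to
   `1 - 1e-7`. The strict upper triangle in row-major order is the feature
   vector — 990 features for 45 ROIs.

# Arm A: classification

**Discriminative power** of a feature is `|tau_b|` between its values and
the binary labels. Tau-b is the tie-corrected variant; with binary labels
the label ties bound the attainable value at `sqrt(n_A n_B / N)` (about
0.71 for 40 + 40), which affects absolute values but no ranking.

**Consensus selection.** Features are ranked within each LOOCV training
fold (the held-out subject never enters its own fold's ranking) and the
top-k (default k = 200) kept; the *consensus set* is the intersection of
all folds' top-k. Because folds share all but one subject the consensus is
typically a large fraction of k. It is a useful stable signature of which
ROI pairs carry group information.

**A caution that the package enforces in its estimators.** Fixing the
consensus set and then running LOOCV with it — the classical presentation
of this pipeline — produces an optimistically biased accuracy: every
consensus feature was conditioned on high rank correlation with label
vectors that include each held-out subject. On pure noise (80 subjects,
990 features) this estimator returns "accuracies" around 0.9. The package
therefore exposes two estimators:

* `loocv_classify(dataset, selection)` — the consensus-fixed estimate.
  Its value is only interpretable against its own permutation null
  (`permutation_test_accuracy()`, nested mode), which shares the bias and
  therefore yields calibrated p values.
* `nested_loocv_classify(dataset, k)` — each fold's SVM uses that fold's
  own training-only top-k. This estimator sits at chance under the null
  and is the number to quote as an absolute accuracy.

**Classifier.** A linear soft-margin SVM (C = 1 by default; the constant is
a config knob, not tuned). The solver is dual coordinate descent on the
Gram matrix with the intercept as a scaled constant input (the liblinear
convention, B = 10), warm-starting every leave-one-out fold from the
full-sample solution. Fold-level predictions agree with `e1071`/libsvm on
all checked datasets; the compiled solver exists because the permutation
test refits on the order of a million SVMs.

**Permutation test.** Labels are shuffled (group sizes preserved) and, in
the default nested mode, the *entire* pipeline — per-fold ranking,
consensus, LOOCV — is rerun per permutation, so selection never sees the
true labels. `p = (1 + #{null >= observed}) / (1 + n_perm)`: the add-one
estimator never returns zero and `>=` counting is conservative. A
non-nested mode (fixed consensus, only classifiers refit) exists for
comparison; note its null centres near chance and is therefore
anticonservative when paired with the biased consensus-fixed observed
value. Under leave-one-out the null accuracy of a fixed feature set sits a
few points *below* 0.5 (training folds are 39-vs-40 imbalanced; libsvm
measures the same), a known LOOCV pessimism worth remembering when reading
null histograms.

Specificity is the accuracy on the first group (the slow-growing-lesion
role), sensitivity on the second; overall accuracy is their mean, which is
insensitive to class imbalance after QC exclusions. A stratified 10-fold
splitter (`kfold_classify()`) is provided as an alternative.

# Arm B: weighted graph topology

Negative correlations are zeroed (the traditional treatment), and the
matrix is thresholded at *proportional sparsity*: keep the
`round(s * n(n-1)/2)` strongest positive edges, for s from 10% to 50% in
steps of 5%. Equating edge count across subjects prevents differences in
overall correlation magnitude from masquerading as topology. Per level:

* **Global efficiency** — mean inverse shortest path length over ordered
  pairs, edge length = 1/weight, unreachable pairs contributing 0 (defined
  on disconnected graphs). The 1/weight mapping is the standard choice for
  correlation-weighted networks; nothing in the method fixes it uniquely.
* **Local efficiency** — per node, the efficiency among its neighbours with
  the node removed, in the weighted formulation with cube-root symmetrized
  weight scaling; nodes with fewer than two neighbours contribute 0.
* **Null normalization.** Both efficiencies are divided by their means over
  (default) 1000 degree-preserving rewired null networks: double-edge swaps
  (~10 attempts per edge) destroy the topology while keeping the degree
  sequence, then the original weight multiset is dealt randomly onto the
  rewired edges — so the weight distribution is preserved exactly. Graphs
  too dense for any legal swap degenerate to a weight shuffle on the fixed
  topology (logged).
* **Modularity Q** — weighted Newman modularity, optimized by multi-level
  greedy moves with seeded random restarts (default 100; best Q wins, ties
  to the first found). The partition is re-estimated at every sparsity
  level; the optimizer matches or exceeds igraph's multilevel Q on random
  graphs and recovers planted partitions.
* **Intra-/intermodular connectivity** — mean edge weight within (resp.
  between) modules divided by the mean over all retained edges, plus their
  ratio. We read the normalization as mean-weight ratios rather than sums:
  sums conflate edge counts with weights, and the mean-ratio form makes
  values near 1 interpretable. A per-module-averaged variant is available
  behind a flag.

Each metric is integrated as the unweighted mean over the sparsity levels
at which it is defined (equivalently, normalized area under the curve on an
even grid). On strongly modular synthetic networks the lowest sparsity
levels can retain *no* between-module edge; the modular-connectivity triple
is then undefined there, recorded as missing, and the subject flagged —
empirical matrices from real recordings are far less block-pure and do not
hit this.

**Group inference.** Per metric, a two-sided permutation test on the group
mean difference (group sizes preserved, add-one p, 10,000 shuffles by
default; the null is drawn from the sorted pooled values so the p value is
exactly invariant to swapping the group roles). Benjamini–Hochberg step-up
across the six metrics at alpha = 0.05. Because permutation tests cannot
adjust for covariates, a parallel ANOVA fits
`metric ~ age + diameter + group` with group entered last; the sequential F
tests the adjusted group effect and classical eta squared (group SS over
total SS) is reported, with partial eta squared behind a flag. With two
covariates the F degrees of freedom are (1, n − 4). Descriptives use the
pooled two-sample t (computable from printed summaries, so published
tables can be checked without raw data) and the Pearson chi-square without
continuity correction for 2×2 counts.

# The synthetic cohort generator

`cohort_config()` fixes the study conditions: 40 subjects per group, 45
ROIs in three 15-ROI modules, 301 timepoints at TR = 1.5 s. Each subject's
panel is drawn as independent multivariate-normal timepoints from a
block-compound-symmetric correlation matrix (unit diagonal, `intra_r`
within modules, `inter_r` between; such matrices are positive semidefinite
whenever `inter_r <= intra_r < 1`, and an eigenvalue-clipping repair with
tolerance 1e-10 guards the numerically indefinite corner). The default
group contrast — group A at (0.45, 0.25), group B at (0.60, 0.15) — was
calibrated once so that group A shows lower within-module and higher
between-module coupling, the qualitative pattern the topology arm is meant
to detect, with means/SDs of the recovered metrics in a plausible range;
it is not adjusted per experiment. Ages (normal, 38.8 ± 10.8 vs
51.3 ± 13.1 years) and lesion diameters (55 ± 19 vs 48 ± 16 mm) follow the
reference cohort moments, truncated to 18–90 years and 5–120 mm. A
baseline offset of 100 against unit-variance fluctuations puts clean
subjects at tSNR ≈ 100, comfortably above the QC gate. Optional confounds —
a shared global signal, linear drift, and spikes — are injected *and*
stored as regressor columns, so the denoising stage can be exercised
end-to-end.

What the generator deliberately does not emulate: temporal autocorrelation
of the haemodynamic response (timepoints are white; every downstream
statistic operates on correlation matrices, for which white generation is
sufficient and keeps the generator analytically checkable), spatial
heterogeneity of edge strengths within a block, scanner drift structure
beyond a linear term, and any voxel-level physics. Passing tests on these
cohorts therefore demonstrate the *estimators'* correctness and
calibration, not that real recordings satisfy the generative assumptions.
One consequence of block purity is worth repeating: real connectivity
matrices have overlapping within/between edge-weight distributions, whereas
sharp blocks can disconnect at low sparsity (see the missing-level handling
above).

# Numerical and reproducibility choices

* One master seed per run; subjects, sparsity levels, null networks,
  restarts and permutations each derive private streams by a counter
  scheme, so any component can be recomputed in isolation bit-identically.
  Compiled code uses its own xorshift generator seeded from R, never R's
  global RNG state.
* Edge-count rounding at thresholding is half-away-from-zero; ties among
  equal weights at the cut break by (row, column) lexicographic order.
* Feature-ranking ties break by ascending feature index; SVM decision
  values of exactly zero resolve to the first group.
* Pearson correlation uses the unbiased (T − 1) variance convention —
  irrelevant to r itself, fixed for reproducibility of intermediates.
* Problem sizes in the test-suite simulations (for example 50 rewired
  nulls and 500 permutations per cohort in the topology calibration suite,
  200 permutations per seed in the classifier calibration suite) are
  reduced relative to the 1000/10,000 analysis defaults; they were chosen
  as the smallest sizes at which the Monte-Carlo error is negligible
  relative to the tested tolerances.

# Known limitations

* The consensus-fixed accuracy is biased upward by construction (see Arm
  A); always report it with its permutation p, or use the nested
  estimator.
* The intercept of the SVM is mildly regularized (scaled-input
  formulation); solutions can differ from an equality-constrained solver
  on knife-edge points.
* Greedy multi-level modularity optimization is a heuristic; with 100
  restarts on 45-node graphs it is effectively exact, but no optimality
  certificate exists.
* The ANOVA assumes linear covariate effects and homoscedastic residuals;
  eta squared is reported from the sequential decomposition with group
  last and will differ from partial eta squared when covariates explain
  variance.
* Voxel-level preprocessing (realignment, normalization, smoothing,
  parcellation) is out of scope: the package starts at ROI time series.
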