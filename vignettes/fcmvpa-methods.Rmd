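---
title: "Methods: whole-brain connectivity group analysis with multivariate pattern classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain connectivity group analysis with multivariate pattern classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmvpa)
```

## The analysis problem

Case-control resting-state fMRI studies often ask two distinct questions
about functional connectivity (FC): *which individual connections differ
between groups* (a mass-univariate question), and *does the joint pattern of
all connections distinguish patients from controls* (a multivariate
question). The two can dissociate: when group differences are weak but
distributed over many edges, every edgewise test can fail its
multiple-comparison correction while a classifier trained on the full
pattern still separates the groups reliably. This package implements both
analyses, plus the bookkeeping needed to interpret a classifier's selected
connections, for time series extracted on a 90-region anatomical
parcellation.

The pipeline operates on *post-preprocessed* ROI time series (T timepoints
by 90 regions per subject). Everything upstream — slice timing, motion
correction, normalization, nuisance regression, band-pass filtering — is
out of scope; those steps belong to dedicated preprocessing suites and
their output is this package's input.

## Parcellation, edges and networks

The atlas is the 90-region cerebral AAL parcellation stored in AAL
numerical order (odd = left, even = right hemisphere). Each of the 45
bilateral region codes belongs to one of six resting-state functional
networks — visual (VN, 14 regions), somatomotor (SMN, 12), attention (AN,
15; the dorsal and ventral attention systems merged), frontoparietal (FPN,
10), limbic (LS, 16) and default mode (DMN, 23) — with one
laterality-split assignment: the right inferior temporal gyrus sits in AN
and the left in DMN. The per-network sizes are fixed invariants of the
atlas and are what make the standardized percentages below exact.

All 90·89/2 = 4005 unordered region pairs are indexed once, in row-major
upper-triangle order, by a single bijection (`edge_index()` /
`pair_of_edge()`) that every module shares. This removes the most common
failure mode of multi-stage connectome pipelines: two stages silently
disagreeing about which vector position is which edge.

Per subject, FC is the Pearson correlation of each pair of regional time
series; the 4005 upper-triangle values are Fisher r-to-z transformed
(z = arctanh r) to stabilize variance and improve normality. arctanh is
undefined at |r| = 1, so the diagonal is excluded by construction and the
synthetic path (where exact collinearity can be constructed) clips at
1 − 1e−12; the real-data path instead raises an error, because |r| = 1
between two distinct regions indicates a data problem worth surfacing.

## Univariate statistics

Edgewise comparison uses the pooled-variance (Student) two-sample t-test,
two-tailed, with the convention t > 0 where controls have larger
connectivity. Pooled variance rather than Welch matches standard
connectome toolboxes and is exact under the equal-n design this kind of
study uses. Three multiple-comparison schemes are provided:

* **Bonferroni**: p·4005 < 0.05.
* **Benjamini–Hochberg FDR** at q < 0.05 (step-up).
* **Network-based statistic (NBS)**: edges with |t| above the two-sided
  critical value at the cluster-defining threshold (default p < 0.001) and
  a consistent sign form a suprathreshold graph per direction; connected
  components are scored by *extent* (edge count); significance comes from
  a permutation null of the maximal extent over both directions under
  random relabelling of subjects, with corrected p floored at 1/n_perm.

Choices worth recording: the cluster-defining test is two-sided and then
split by direction (the defining publications treat each contrast
one-sided; splitting a two-sided threshold by sign is the reading that
matches "cluster-defining threshold of p < 0.001 by two-sample t-tests"
and keeps both directions at the same critical value); the component
statistic is extent, the original NBS default, not intensity; and null
maxima are pooled across both directions so the family-wise error rate
covers the full two-sided family. An `exhaustive = TRUE` mode enumerates
every label assignment, which is feasible for small groups and is how the
engine is verified against brute-force enumeration in the tests.

## The classifier

The multivariate analysis is a linear soft-margin SVM under
leave-one-subject-out cross-validation (LOOCV) with *nested* univariate
feature selection:

1. In each fold, the held-out subject is removed first. On the remaining
   subjects only, each edge gets a two-group one-way F score (for two
   groups, F = t²); edges are ranked by descending F, ties broken by
   ascending edge index for cross-platform determinism.
2. For each percentage N on the grid (10%, 20%, …, 100%), the top
   floor(N/100·4005) edges are kept — floor, so N = 10% keeps exactly 400
   edges — and a linear SVM (cost C = 1, no internal standardization) is
   trained and applied to the held-out subject.
3. Pooling the held-out predictions gives accuracy, sensitivity and
   specificity per percentage (patients are the positive class). The final
   accuracy is the maximum over the grid; ties go to the smallest
   percentage (parsimony).

Feature selection inside every fold is the point: ranking on all subjects
and cross-validating only the SVM would leak the test subject into the
selection statistics and optimistically bias the accuracy. A dedicated
test constructs data where the leaky and non-leaky rankings provably
differ and asserts the non-leaky one is used.

Labels are coded controls = +1, patients = −1. Consequently a *positive*
SVM weight marks an edge whose larger Fisher-z value pushes the decision
toward controls — i.e. connectivity that is lower in patients — and a
negative weight the reverse. All downstream sign language (positive vs
negative weighted degrees) inherits this convention.

**Inference.** Because the final accuracy is a maximum over ten
percentages, its null distribution must be the null distribution of that
maximum. Each permutation therefore reruns the *complete* nested procedure
— ranking, selection at every grid point, training — with shuffled class
labels, and records its own maximum accuracy over the grid. Comparing each
true per-percentage accuracy against these maxima yields family-wise-error
corrected p-values directly, floored at 1/n_perm. The default shuffling is
*within each fold's training set* (each fold draws its own shuffle);
a `"global"` mode that draws one shuffled label vector per permutation is
also exposed. With very small cohorts the global mode occasionally redraws
the true labelling, which is a property of the null, not a bug.

The ROC curve pools held-out decision values at the best percentage
(patient-ness score = −decision value) and sweeps a threshold, grouping
tied scores; the AUC uses the rank (Mann–Whitney) formula with average
ranks on ties, which equals the trapezoidal area under the tie-grouped
curve. The SVM itself is fitted by libsvm (via e1071) with a tight
termination tolerance (1e−6) and is checked in the tests against an
independent quadratic-programming solve of the dual.

## Characterizing the selected edges

The selected-edge set is the union, over folds, of the edges chosen at the
best percentage, each with its mean SVM weight over the folds that chose
it and its selection frequency. Three summaries follow:

* **Weighted degrees**: per region, the sum of positive weights and
  (separately) negative weights of incident selected edges. Each edge
  contributes to both endpoints, so degrees per sign sum to exactly twice
  the corresponding weight sum — an identity the tests assert. Highlight
  thresholds (mean ± 1·SD and ± 2·SD) are computed over all 90 regions,
  zeros included, since every region is plotted in this kind of figure; an
  absolute-value mode for the negative side is available because published
  figures are ambiguous on this point.
* **Network summary**: each selected edge is classified by its endpoints'
  networks; counts per (unordered) network pair are standardized by the
  number of *possible* pairs of that kind and expressed as percentages.
  The intra-network and inter-network means are pooled
  (100 · total count / total possible, with 680 possible intra- and 3325
  possible inter-network edges), not averages of per-network percentages.
* **Clinical correlations**: Pearson r of each selected edge against each
  requested clinical variable (defaults: the apnea-hypopnea index and the
  percentage of sleep time below 90% oxygen saturation), *within patients
  only*, flagged at uncorrected p < 0.005. That liberal uncorrected
  threshold mirrors common practice in small cohorts; BH q-values over all
  tested pairs are emitted alongside for users who prefer corrected
  inference.

## The synthetic cohort generator

There is no public dataset at this design's scale, so the package carries
a generator that defines its own ground truth; every calibration and
recovery claim in the tests is a claim about these conditions.

Controls are multivariate normal with a block correlation structure:
`rho_in` (default 0.3) within each functional network, `rho_out` (default
0.1) between networks, values typical of band-passed BOLD data on an
anatomical parcellation. Patients share the structure except on a
designated edge set, shifted by `effect_delta`. Arbitrary edge shifts can
destroy positive definiteness, so the shifted matrix is repaired to the
nearest correlation matrix (Higham alternating projections via
`Matrix::nearPD`); the achieved shift on every effect edge is then
verified, and the generator *rejects* specifications whose repair moved
any effect edge by more than half the request rather than silently
simulating a weaker effect than advertised. In practice this means large
effects must be placed coherently: `subnetwork_effect_edges()` places k
edges as the pairwise connections of a region subset, which acts like an
added latent factor and stays near positive definite, whereas the same
number of randomly scattered shifted edges does not. A coherent aberrant
subnetwork is also the more realistic disease model.

Temporal structure is AR(1) (default coefficient 0.3, mimicking the
smoothness of band-passed BOLD). The AR filter is applied to independent
innovations *before* the spatial mixing (Cholesky factor of the target
correlation), so the population spatial correlation is preserved exactly
regardless of the temporal filter — the tests check both properties at
long T. Defaults are 21 subjects per group and 170 timepoints, a typical
single-site design.

Clinical variables follow group-specific marginals (normal, clamped to
physiological ranges, for age, education, BMI, the cognitive screening
score and the sleepiness scale; log-normal for the right-skewed
apnea-hypopnea index and percentage of desaturated sleep time) with means
and SDs typical of a moderate-to-severe patient group against healthy
controls. A clinical link ties a patient variable to a designated edge via
a Gaussian copula on the subject's *observed* Fisher-z edge value. A
monotone marginal transform attenuates Pearson correlation, so for
log-normal marginals the latent correlation is inflated analytically by
the known factor (corr(X, e^{sY}) = r·s/√(e^{s²}−1)) and the target r is
attained in expectation on the observed scale; targets requiring a latent
correlation beyond 0.99 are capped with a warning.

What the generator does **not** emulate: head motion and physiological
noise, non-Gaussian BOLD marginals, spatially varying hemodynamics,
subject-level variation in the population correlation structure, and
site/scanner effects. Passing the recovery and calibration suites
therefore shows the *procedures* are correct and calibrated under a
faithful null and a controllable alternative; it does not certify effect
sizes or accuracies on real cohorts, whose headline numbers depend on
acquired data this package cannot ship.

## Numerical and reproducibility choices

* Degenerate edges (zero pooled variance) get NA statistics and are
  excluded from significance masks; a zero within-group variance with
  distinct group means yields F = +Inf, ranked first and flagged.
* Decision-value ties at exactly 0 predict the control class; F-score ties
  rank by ascending edge index; best-percentage ties take the smallest
  percentage. All tie-breaks are deterministic.
* Permutation p-values are floored at 1/n_perm (never exactly zero);
  exhaustive enumeration has no floor because the identity relabelling is
  included.
* One global seed drives everything; the pipeline expands it into
  independent per-stage seeds (cohort, NBS, classifier permutations) so
  stages rerun in isolation reproduce their results. Rerunning the full
  pipeline with the same configuration and seed rewrites every result
  file byte-identically (the manifest, which logs wall times, is the one
  deliberately excluded file).
* Problem sizes in the test suite are chosen to keep the full run around
  ten minutes on one core: family-wise-error calibration of the classifier
  uses 100 null cohorts of 4+4 subjects on 8 regions with a {50%, 100%}
  grid at 200 permutations; NBS calibration uses 50 null cohorts of 10+10
  subjects on 10 regions at 1000 permutations; the null rejection-rate and
  effect-recovery checks run at full study scale (21+21, 90 regions,
  T = 170). Calibration assertions bound the observed family-wise rates by
  0.05 plus three binomial standard errors, the valid-and-conservative
  direction for max-statistic tests.

## Known limitations

* Pooled-variance t assumes equal group variances; with equal n the test
  is robust, but strongly unequal designs would warrant a Welch option.
* No covariate adjustment (age, BMI) in the edgewise tests — deliberate,
  to match the analysis this pipeline reproduces — and no partial,
  wavelet or dynamic connectivity.
* The SVM cost is fixed at C = 1 with no nested hyperparameter tuning and
  no feature standardization; both are visible, overridable defaults
  rather than optimized choices.
* LOOCV accuracy estimates on 42 subjects are high-variance; the
  permutation test quantifies significance, not stability. Repeated
  k-fold schemes are out of scope.
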