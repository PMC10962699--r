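---
title: "Methods: triplet similarity, RSA, overlap, and commonality analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triplet similarity, RSA, overlap, and commonality analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripletrsa)
```

# What this package computes

`tripletrsa` implements a behavioral-and-neural representational similarity
analysis (RSA) pipeline for studying object-category selectivity — in
particular, designs that contrast graspable food items with tools and other
manipulable artefacts. The pipeline has five statistical stages:

1. **Behavioral RDMs from odd-one-out triplets.** Participants see three
   objects and pick the one unlike the other two. The dissimilarity of a
   pair (i, j) is the fraction of trials containing both in which either
   was picked. Reliability is estimated by split-half correlation with
   Spearman–Brown correction.
2. **Likert rating tasks.** 1–7 ratings are averaged per stimulus, given
   split-half reliabilities, correlated across tasks, and summarized by a
   two-component PCA of the task profiles.
3. **Neural RDMs and RSA.** Stimulus-by-voxel response patterns become
   1 − r correlation-distance RDMs; RDMs from any modality are compared by
   Spearman correlation of their lower triangles, with a leave-one-out
   noise ceiling and nonmetric MDS for visualization.
4. **Map-level spatial analysis.** ROIs are defined from statistical maps
   by an adaptive threshold-plus-cluster rule; the spatial convergence of
   two selectivity maps is quantified by the Jaccard index and by top-N
   voxel overlap curves.
5. **Commonality analysis.** The explained variance of a three-predictor
   regression of the group-averaged RDM is partitioned into unique and
   shared components, with a row-shuffle permutation test for the full
   model.

Every stage can be exercised end-to-end on synthetic data with known
ground truth; the generators are first-class, tested code.

# The stimulus design and model RDMs

The default design has 48 stimuli: 8 exemplars in each of 6 groupings
(food items, food tools, other-directed tools, self-directed tools,
manipulable objects, animals), with the shape profile counterbalanced so
that each grouping holds 4 elongated (high aspect ratio) and 4 stubby
(low aspect ratio) exemplars. Ordering is type-major, aspect-ratio-minor,
so every serialized matrix is reproducible.

Two dummy-coded predictor RDMs express the design:

* the **object-type model** assigns a dissimilarity level to each pair of
  superclasses (food, artefact, animal). The numeric levels of this coding
  are not identified by rank-based RSA — any order-preserving relabeling
  gives identical Spearman comparisons — so the package uses the simplest
  coding consistent with food being intermediate between artefacts and
  animals: within-superclass 0, food–artefact 1, anything–animal 2. The
  coding is an explicit argument for sensitivity analyses. Food–food pairs
  take level 0 because the model describes between-superclass structure
  only.
* the **shape model** is the binary aspect-ratio coding: 0 for same
  elongation class, 1 otherwise.

Counterbalancing makes the two models nearly orthogonal; on the default
design their lower-triangle Spearman correlation is:

```{r}
d <- build_default_design()
compare_rdms(make_type_model_rdm(d), make_shape_model_rdm(d))$rho
```

# Triplet aggregation, quality control, and reliability

With 48 stimuli there are `choose(48, 3) = 17296` unique triplets,
chunked (seeded permutation) into sets of 42 with one remainder set of 34.
Quality control drops a participant-session when all its choices were the
same response position, or all the same stimulus (both readings of
"responded uniformly" are applied — the conservative superset), or when
the session's median reaction time falls below 200 ms or above 10 s.

The split-half reliability routine splits by trial by default; a
session-level split is available because in designs like this one a
session is one chunk completed by one participant, so sessions are the
natural exchangeable unit. The correlation inside a split is Pearson
(Spearman is an option), computed over pairs defined in both halves —
pairwise deletion rather than imputation, which is unbiased under random
splits. The mean split correlation is Spearman–Brown corrected,
`2r / (1 + r)`, to estimate full-sample reliability.

A caution established while validating the package: in the
zero-decision-noise limit the aggregated proportion for pair (i, j)
equals the fraction of third stimuli k with `d(i,j) > min(d(i,k), d(j,k))`.
This is a monotone-like but not rank-preserving functional of the
generating matrix, and it quantizes to n − 2 levels, so even noise-free
full-enumeration data recover the generating ranks strongly
(ρ ≥ 0.9 at n = 48) but not perfectly. Tests assert the attainable
property, not exact rank identity.

# Rating analysis

Mean ratings are reported per stimulus and per object type with 95%
normal confidence intervals (mean ± 1.96 SEM). Rating reliability splits
participants — the only sensible unit, since each participant rates each
stimulus once. The PCA of the four action-task profiles z-scores each
task before decomposition: the tasks share a 1–7 scale but differ in
spread, and the correlation-matrix convention keeps loadings comparable.

# RDM comparison, noise ceiling, and MDS

Neural RDMs use the 1 − r Pearson correlation distance (range [0, 2]);
constant patterns yield flagged `NA` entries rather than silent zeros.
Comparisons between RDMs are Spearman correlations of the row-major
lower-triangle vectors over jointly defined pairs, making every
comparison invariant to monotone transforms of either RDM.

The noise ceiling is the leave-one-out lower-bound style: each
participant's lower triangle is Pearson-correlated with the mean of the
others', and the coefficients are averaged. No upper-bound variant is
computed — the pipeline's group inferences use the lower bound only.
Group-level tests on RDM correlations are two-sided t-tests across
participants' coefficients, on raw coefficients by default with a
Fisher-z option.

MDS is nonmetric with Kruskal's stress-1 criterion (the criterion that
matches the toolboxes this pipeline interoperates with), run from a
classical-scaling start plus 7 random restarts under the caller's seed;
the lowest-stress configuration is returned with its stress as a
fraction. Exactly embeddable distances reach stress ~0; zero
off-diagonal dissimilarities are nudged by a negligible epsilon because
the monotone regression requires positive dissimilarities.

# ROI definition and overlap

Cluster connectivity is 18-neighbor (faces and edges, not corners)
everywhere, including the overlap analysis. The adaptive ROI rule walks
the threshold ladder 0.001, 0.005, 0.01, 0.05 from most stringent to
most liberal; at each step the suprathreshold voxels inside the
anatomical mask are clustered and clusters under 40 voxels discarded
(cluster-then-count at every step); the first threshold with survivors
defines the ROI, and if none survives the most liberal threshold, no ROI
is created. "Masking" is set intersection with the anatomical mask.

The thresholded overlap of two maps applies the liberal threshold
(p < 0.05, cluster 40) to each and takes the Jaccard index of the
surviving sets, with the two unique fractions sharing the union
denominator so the three numbers sum to 1. A participant whose
thresholded map is empty is *undefined* and excluded from group means —
mirroring how such participants reduce the analyzable N — never recorded
as zero overlap. The top-N curve selects the n most selective voxels per
map (by the contrast statistic, ties broken by linear voxel index, no
clustering) for n = 50 … 500 in steps of 50.

# Commonality analysis

For predictors a, b, c, ordinary least squares with an intercept is fit
for all seven nonempty subsets, and the seven R² values are combined by
the standard weighting identities into U(a), U(b), U(c), C(ab), C(ac),
C(bc), C(abc). The components sum to the full-model R² by construction
(asserted to 1e-10 in the tests); negative commonalities are legal
(suppression) and reported as-is. Predictors enter raw (unranked), and
shares are also reported as percentages of explained — not total —
variance.

The permutation test shuffles, for each participant independently, each
row of the strictly-lower-triangular array of their RDM (row i holds the
dissimilarities of stimulus i to stimuli 1…i−1), averages the shuffled
vectors across participants, and refits the full model; 1000 iterations
by default. The text this scheme descends from is ambiguous about ragged
triangular rows, so a whole-vector permutation is available as a
sensitivity option (`scheme = "vector"`). A p-value with zero
exceedances is reported as `< 1/n_perm`, the standard permutation
convention, rather than 0. Because R² is invariant to affine transforms
of the response, the test is invariant to common linear rescalings of
the participant RDMs.

# The synthetic generators

The generators produce every input the pipeline consumes, with the
statistical structure the analysis assumes — and deliberately nothing
more:

* **Ground truth.** A weighted sum of the type and shape model RDMs,
  rescaled to [0, 1]. Defaults are `type_weight = 1`,
  `shape_weight = 0.25`: object type dominant with shape as a weaker
  secondary factor, the qualitative regime the behavioral tasks this
  pipeline serves are designed to reveal.
* **Triplet choices.** A Luce-style softmax over "oddness" (the summed
  dissimilarity of a stimulus to the other two) with temperature 0.05
  and a 2% lapse rate by default; temperature 0 is the argmax limit.
  Reaction times are log-normal with configurable median — only the
  median matters to the QC rule, so no attempt is made at realistic RT
  shapes.
* **Ratings.** True score plus participant offset (SD 0.5) plus trial
  noise (SD 1), rounded and clipped into 1–7; 40 participants per task,
  matching typical online rating-task samples.
* **Voxel patterns.** Each voxel's profile across stimuli is multivariate
  normal with stimulus covariance `1 − truth`, projected to the nearest
  positive semidefinite matrix (eigenvalue clipping) so arbitrary truth
  RDMs give valid sampling distributions, plus independent Gaussian noise
  (SD 0.2 by default) per entry; 200 voxels per region, 20 participants.
* **Statistical maps.** Two Gaussian-profile blobs (peak 8, width 3
  voxels) on a 24³ grid, centers displaced along one axis, with optional
  background noise; the noise-free suprathreshold sets provide an exactly
  countable true Jaccard index.

All generators are deterministic given the seed; per-participant streams
are derived from it so participants are mutually decorrelated.

What the generators do **not** emulate — and hence what passing tests do
not establish about real data: spatial autocorrelation and hemodynamics
in the maps (blobs are smooth and isotropic, real selectivity maps are
not), session and attention effects in behavior beyond lapses, item-level
semantic structure within a category, and any systematic relation between
behavioral and neural noise. The recovery results certify the estimators,
not the biology.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use deliberately modest
sizes — one full triplet enumeration (17,296 trials), 12 simulated
participants at 200 voxels for the neural route, 20 replicates for the
unique-share comparison, 50 null replicates at 200 permutations for the
type-I check — sizes at which the checked properties are already stable
while the whole suite runs in well under a minute per stage.

Other numerical conventions: RDM symmetry is enforced by averaging with
the transpose after an exact-tolerance check; Spearman p-values are
asymptotic (ties make exact ones unavailable); `lm.fit` handles
rank-deficient commonality designs with a warning rather than an error;
top-N ties break by linear voxel index; MDS restarts default to 8.

# Known limitations

* The commonality machinery is fixed at three predictors — the weighting
  table implemented is the three-predictor one.
* The noise ceiling has no upper-bound variant.
* The ROI machinery operates on voxel grids only; surface-based analysis
  is out of scope.
* `aggregate_rdm` treats every trial as exchangeable; it does not model
  participant-specific response biases when pooling.
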