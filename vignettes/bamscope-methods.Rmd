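---
title: "Methods: brain activity map screening and functional prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: brain activity map screening and functional prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening model

`bamscope` implements a phenotypic drug-screening pipeline for larval
zebrafish whole-brain calcium imaging. A compound's phenotype is a **brain
activity map (BAM)**: for every region of interest (ROI) at row $i$, column
$j$, the change in the number of detected calcium transients between the
pre- and post-treatment epochs, summed over imaged z-planes $k$:

$$a_{ij} = \sum_k c^{t_1}_{ijk} - c^{t_0}_{ijk}.$$

With $n$ biological replicates (default $n = 5$ larvae per compound), the
per-ROI evidence of a reproducible drug effect is a one-sample T statistic,
the **T-score BAM**:

$$t_{ij} = \frac{\overline{a_{ij}}}{s_{a_{ij}} / \sqrt{n}},$$

where $\overline{a_{ij}}$ and $s_{a_{ij}}$ are the replicate mean and SD.
Downstream, every T-score BAM is reduced to a 20-dimensional **Pheno-Print**
(its coefficients on the top 20 principal components of the training
library), drug phenotype clusters are discovered by consensus clustering
over bootstrap-resampled hierarchical clusterings, clusters are linked to
WHO ATC level-2 therapeutic categories by the hypergeometric upper tail,
and unlabeled compounds are assigned to clusters by a 100-tree random
forest and ranked by the Pearson correlation between their Pheno-Print and
the **signature subgroup** centroid (the cluster members that hold the
associated category).

The pipeline's assumptions, in order of load-bearing weight:

* drug effects are reproducible across larvae at the ROI scale, so the
  replicate T statistic concentrates on genuinely modulated regions;
* phenotypic similarity in Pheno-Print space is informative about shared
  CNS pharmacology, so cluster membership transfers a therapeutic label;
* the training library is large and category-diverse enough that a
  cluster/category overlap beyond hypergeometric chance is meaningful.

## From movie to counts

* **Meshing.** Frames are tiled into square ROIs of 15.21 µm² (a 3 × 3
  block of 1.3 µm pixels). `mesh_rois()` requires an integer pixel block
  and names the nearest valid area otherwise, since the published ROI area
  only tiles a sensor at particular pixel sizes.
* **Filtering.** Each ROI trace is high-pass filtered at 0.2 Hz with a
  zero-phase second-order Butterworth filter (`signal::filtfilt`), removing
  illumination drift. The trace mean is subtracted before filtering because
  `filtfilt` does not estimate initial conditions and would otherwise leak
  a DC edge transient into the output.
* **Transient detection.** ΔF/F is the filtered fluctuation divided by the
  epoch-mean baseline $F_0$ of the unfiltered trace (the baseline definition
  is a design choice; a rolling-percentile baseline was considered and
  rejected as unnecessary at these trace lengths). Events are upward
  crossings of a threshold at mean + 2 SD of the ΔF/F curve, separated by a
  1 s refractory period. Because the threshold self-scales, it collapses to
  twice the noise SD in an epoch that a drug has silenced and then counts
  camera noise (about 1% of samples for Gaussian noise); the optional
  `min_amplitude` floor (e.g. 0.05 ΔF/F, the smallest credible transient)
  suppresses that failure mode and is used in the movie demonstration,
  while the default keeps the pure mean + 2 SD rule. A trace whose ΔF/F SD
  is below 10⁻⁹ is treated as flat (zero events) so numerical jitter on a
  constant trace is never counted.
* **Registration.** The mean pre-treatment image is registered to an
  elliptical brain template by coarse-to-fine grid search over a similarity
  transform (rotation ±20° at 0.5° resolution, translation, isotropic
  scale), maximizing Jaccard overlap of the Otsu-thresholded foreground
  with the template mask plus the left–right mirror correlation about the
  template midline. Eye-region ROIs are dropped after registration. Grid
  search was chosen over gradient methods because the objective is
  piecewise constant in the overlap term and the search space is tiny.
* **Rate normalization.** The default epochs are 10 min pre and 15 min
  post treatment. Counts are rate-normalized to a common 10-min reference
  (and rounded back to integers) before differencing, so unequal epoch
  durations compare like with like; normalization can be disabled.

## T-score numerical policy

BAM entries are integer count differences, so all five replicates of a ROI
can coincide exactly, giving SD = 0. The policy is: mean = 0 gives t = 0;
mean ≠ 0 floors the SD at `eps = 1` — one count, the rounding quantum.
Replicate agreement tighter than one count is quantization, not evidence,
and the floor caps the statistic at $\sqrt{n}\,|\overline{a_{ij}}|$, on the
same scale as genuine T values. A much smaller floor would let a handful of
degenerate ROIs reach |t| of several thousand and dominate the PCA and all
Euclidean distances; measured on the default synthetic library, a floor of
10⁻³ produced |t| up to 3.8 × 10⁴ in 17 ROIs and destroyed cluster
recovery entirely.

## Pheno-Prints

PCA is fitted on mean-centered flattened maps with no per-ROI scaling:
T-scores already share a unitless scale, and rescaling would inflate
template-silent ROIs. Components are computed by exact singular value
decomposition (`stats::prcomp`) for determinism, and each loading's sign is
fixed so its largest-magnitude entry is positive, making Pheno-Prints
reproducible across platforms. Raw (unscaled) coefficients feed the
clustering; weighting by explained variance was considered and rejected
because Euclidean distance on raw coefficients equals distance in map space
restricted to the component subspace, which is the quantity of interest.

## Consensus clustering and choosing k

Each of 1000 iterations draws 80% of compounds without replacement
(classical bootstrap resampling is available as an option) and clusters
them by average-linkage agglomerative clustering on Euclidean Pheno-Print
distances; the tree is cut at every candidate k in 2..15. The consensus
matrix entry for a pair is the fraction of co-clustered iterations among
co-sampled ones. Final labels cut an average-linkage tree built on
1 − consensus.

k is selected by the area under the empirical CDF of consensus entries
(upper triangle, trapezoidal rule): the smallest k from which onward the
relative AUC increase stays below 1% **for every subsequent step**. The
"every subsequent step" qualifier matters: single-step increments fluctuate
around zero below the true k (cluster merge order is ambiguous under
resampling), and the one-step rule can fire spuriously at small k. The 1%
threshold is scale-dependent — splitting one compound off a cluster moves
the AUC by roughly (cluster size − 1) / (number of pairs) — so a library
must be large enough that this quantity is below the threshold at the true
k; 179 drugs in 10 clusters satisfies this comfortably, while the 40-drug
down-scaled test scenario uses a 5% threshold for the same reason.

Per-drug cluster coherence is a one-tailed rank-sum (Mann–Whitney) test of
the drug's consensus scores against in-cluster versus out-of-cluster drugs,
BH-adjusted across drugs, with a Pheno-Print-distance variant reported
alongside. A *signed-rank* test is not applicable to these unequal-size
groups, so the rank-sum form is used; consensus scores are heavily tied, so
the normal approximation with tie correction is used throughout.

## ATC association and prediction

The hypergeometric p-value for a (cluster, category) pair is
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ with $N$ training
drugs, $K$ category holders and $n$ cluster members. Drugs holding several
level-2 codes count toward each (a "primary code only" mode exists);
significance is nominal at α = 0.05 with no multiplicity correction,
matching the screening convention of treating the 10 × 7 grid as a
hypothesis-generating scan — a BH-adjusted column is emitted for readers
who want it. Because the test statistic is discrete, its attainable size is
strictly below the nominal level at these margins (typically 0.02–0.04);
the type-I-error property tests therefore compare Monte-Carlo rejection
rates against the exactly computed attainable size, not against 0.05.

Prediction is two-step: a 100-tree random forest (the standard
implementation in the `randomForest` package, default mtry = ⌊√20⌋,
deterministic given a seed) assigns each test compound to a cluster by
majority vote (ties broken toward the lowest label, logged), and compounds
in ATC-associated clusters are ranked by the Pearson correlation between
their Pheno-Print and the signature centroid of the cluster's most
significant category. Compounds in non-associated clusters carry no score;
a zero-variance Pheno-Print has no defined correlation and is ranked last.

## The synthetic-data generator

No public accession exists for the original recordings, so every stage is
exercised on a generator with planted ground truth. Its defaults are the
study conditions: 179 training drugs and 121 test compounds in 10 latent
clusters, 5 replicates each, a 50-replicate DMSO arm, 7 ATC categories
linked to clusters with 60% purity, and a 60 × 40 ROI grid over 2
z-planes.

Cluster effect templates are smooth signed maps built from 3–5 contiguous
blocks (full-width horizontal bands and mirrored lateral patch pairs),
mirror-symmetric about the midline, normalized to unit mean absolute
amplitude over affected ROIs, and rejection-sampled until all pairwise
correlations are below 0.5 — emulating the region-patterned excitation /
suppression maps that motivate the method. A replicate BAM is
`template × effect_amplitude + drug offset + replicate noise`, rounded to
integers. The noise scales are calibration constants, not measured facts:
`effect_amplitude = 8` counts with `within_cluster_sd = 2` and
`replicate_sd = 4` place the per-ROI replicate T statistic near 4.5 in
affected regions, which makes the pipeline-level outcomes (cluster-number
recovery, > 50% top-20 PC variance, ≥ 90% re-acquisition agreement)
achievable but not trivial. Movies add a further layer: per-ROI
inhomogeneous Poisson events convolved with a 0.1 s-rise / 1 s-decay
indicator kernel, slow sinusoidal illumination drift and white pixel noise.

What the generator does **not** emulate — single-neuron structure, motion
and hemodynamic artifacts, non-Gaussian and spatially correlated noise,
dose dependence, multi-modal drug effects, overlapping or hierarchical
category structure — bounds what passing tests show: they validate the
computational pipeline against a known truth of matching statistical
shape, not the biological performance of the assay on real recordings.

## Problem sizes and determinism

The test suite runs the full default library (179 + 121 compounds, 2400
ROIs) with 250 consensus resamples — 250 is enough for the AUC sequence to
stabilize, and the outcome is required to match the 1000-resample run —
and down-scales to 40 drugs / 4 clusters / 320 ROIs for unit-level checks.
The acceptance script uses the full 1000 resamples. All randomness flows
through a single master seed via `derive_seed(seed, stage)`, so any stage
can be reproduced in isolation; identical configurations and seeds yield
bit-identical libraries, consensus matrices and prediction tables.

## Known limitations

* Registration is 2-D similarity only; no atlas, no nonrigid deformation.
* The transient counter is a threshold detector, not spike inference; its
  counts are biased low at high event rates (kernel overlap) and the
  default rule overcounts silenced epochs under white noise (see
  `min_amplitude`).
* The AUC-CDF rule's 1% threshold is tied to library size (above).
* Hypergeometric association treats categories independently; a drug with
  several codes contributes to each, which slightly inflates category
  sizes relative to a single-label design (configurable).
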