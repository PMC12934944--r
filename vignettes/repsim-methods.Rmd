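---
title: "Methods: representational similarity analysis with variance partitioning"
author: "repsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representational similarity analysis with variance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis model

`repsim` implements a full representational similarity analysis (RSA)
pipeline for condition-by-voxel fMRI response patterns, of the kind used to
ask which candidate computational models explain the representational
geometry of visual and social brain regions.

The central object is the representational dissimilarity matrix (RDM): for
any source of per-condition vectors — voxel patterns in a region, model
embeddings, behavioral rating proportions, motion-energy features — the RDM
entry for a pair of conditions is `1 - Pearson r` between their vectors, a
correlation distance in `[0, 2]`. RDMs from different sources are compared
on their vectorized strictly-upper triangles with Spearman's rank
correlation (average ranks for ties; ties are unavoidable with, e.g.,
one-hot RDMs that take only two distinct values).

**Variance partitioning.** When several candidate models correlate with the
same region, each model's *unique* contribution is estimated with a
semi-partial (part) Spearman correlation: all RDM vectors are
rank-transformed, the predictor model's ranks are residualized on an
intercept plus the ranks of every other model by least squares, and the
statistic is the Pearson correlation between the neural RDM's ranks and the
predictor residuals. The neural target is deliberately *not* residualized —
the statistic answers "how much of the neural geometry does this model
explain that no other model can", which is the part-correlation, not the
partial-correlation, question. With no controls the statistic reduces
exactly to the full Spearman correlation. A predictor that is numerically
collinear with its controls has no unique variance left; its semi-partial
is reported as 0 rather than as an error, so that degenerate model sets
fail softly in group summaries.

**Group inference.** Per-subject statistics are combined with a sign-flip
permutation test of the group mean: under the null the sign of each
subject's statistic is exchangeable, so the null distribution is built from
random sign assignments. When `2^n` fits within the requested permutation
count the full enumeration is used and the p-value is exact; otherwise a
seeded Monte-Carlo sample is drawn and the observed pattern is counted into
the null (`p = (1 + #extreme) / (n_perm + 1)`), which keeps p strictly
positive and the test valid. ROI analyses test one-tailed (is the mean
correlation above zero), model-comparison tests are two-tailed on paired
differences. Multiple testing is controlled with Benjamini–Hochberg FDR;
because the FDR family changes results, each pipeline fixes and records its
family explicitly: across voxels for searchlight maps, across (ROI × model)
cells per statistic kind for ROI tables, and across (window × model) cells
for time-resolved profiles. Group maps are rendered as z-statistics derived
from the FDR-adjusted p-values, signed by the group mean, and additionally
thresholded at |z| ≥ 1.96; the manifest records that z is computed from
adjusted rather than raw p, since the convention is ambiguous.

An optional switch applies the Fisher z-transform to per-subject
correlations before the group test; it is off by default because the
sign-flip test does not require it and the untransformed mean is the
quantity displayed.

**Time-resolved analysis.** When responses are estimated separately in five
consecutive time windows, the unique-variance statistics are computed per
window and the model-by-window interaction is tested with a two-way
within-subject ANOVA (each effect against its own subject-by-effect error
term; for n subjects, 2 models, and 5 windows the interaction df are
(4, 4(n−1)), e.g. (4, 96) at n = 25). No sphericity correction is applied,
and the output metadata says so.

# Volumetric machinery

Searchlights are spheres in voxel units (inclusive boundary,
`dx² + dy² + dz² ≤ r²`): the radius-3 sphere deep inside a solid mask
contains exactly 123 voxels. Both searchlight centers and members are
restricted to the analysis mask; spheres at mask edges keep whatever
members fall inside, and spheres smaller than 10 voxels are computed but
flagged so users can filter them. Functional ROIs are the top
`ceiling(pct·n)` voxels of a localizer contrast inside an anatomical
parcel, with threshold ties broken by lexicographic voxel order so the ROI
is deterministic. Overlap between ROIs is quantified with the DICE
coefficient, and `remove_overlap()` deletes shared voxels from both
regions. Voxel indices are 1-based integer triples throughout, the natural
convention in R; NIfTI affines are carried as metadata for I/O round-trips
but play no role in the geometry.

Before RSA, each voxel's responses are standardized to zero mean and unit
variance across all conditions and repeats within subject, then averaged
across repeats per condition. Split-half reliability divides repeats into
first/alternate halves (positions 1, 3, 5 vs 2, 4; the extra repeat of an
odd count stays in the first half), and the liberal per-voxel mask keeps
voxels with split-half r > 0 — subject-specific for ROI analyses, mean
across subjects for searchlights. The ROI-level noise ceiling is the
Spearman correlation between the two split-half RDMs, projected to the full
data length with the Spearman–Brown formula `2r/(1 + r)`; ROIs whose
ceiling is not significantly above zero are flagged (`ceiling_ok = FALSE`)
and should not be interpreted.

# Non-neural RDM sources

Behavioral RDMs come from per-video category rating counts (friendly,
neutral, adversarial) normalized to proportions — a representation that
preserves rating ambiguity (8/0/2 raters map to (0.8, 0, 0.2)) — or from
one-hot vectors of single categorical judgments. Model RDMs are ingested
from delimited tables of per-condition embedding vectors, treated as
opaque.

The low-level visual control is a motion-energy model: a bank of
quadrature-pair spatiotemporal Gabor filters (default 3 spatial frequencies
× 2 temporal frequencies × 4 motion directions, plus one static low-pass
channel), with per-frame energies spatially pooled over a tiling of the
image. Temporal kernels with nonzero frequency are exactly zero-mean, so
static input produces exactly zero motion energy; energy is quadratic in
contrast; and a drifting pattern excites most the channel matched to its
direction and spatiotemporal frequency. The published analyses this
emulates used an external filter bank with its own fixed geometry; the
pipeline's claims rest on the RDM machinery, not on a particular bank, so
the bank here is small, documented, and configurable. Framewise energies
are reduced with PCA fitted across the frames of *all* videos pooled (a
per-video fit would make representations non-comparable), then averaged
across frames within video. Retention supports both a fixed component
count (default 128) and a variance target; fixed count is the default
because it pins dimensionality reproducibly. An optional `log1p` transform
before PCA is off by default. When a fixed count exceeds the data's rank
the missing dimensions are zero-padded, since they carry exactly zero
variance.

# Stimulus-subset selection

To choose a stimulus set on which two candidate models are distinguishable,
random subsets of fixed size are sampled without replacement and scored by
`w_a·r(A, behavior) + w_b·r(B, behavior) − w_ab·r(A, B)` over the subset's
three RDMs, with category balance (max minus min category count ≤ 4, a
bound consistent with a 16/19/15 split of 50) enforced as a hard
constraint. The source procedure states the four criteria but not how they
were combined; the linear composite with default weights (1, 1, 1) is the
simplest reading that reproduces all stated directions, and the audit table
of every sampled subset's component correlations makes any alternative
weighting easy to re-score after the fact.

# The synthetic-data generator

The generator embodies the inferential premise of model–brain RSA: within
a region of interest, the neural representational geometry is a weighted
blend of candidate-model geometries plus noise. It produces every input the
pipeline consumes — rating-count tables, model representation sets with
controlled inter-RDM correlations, and multi-subject, multi-repeat
volumetric pattern datasets with planted regional geometry, optionally
varying over five time windows — so every end-to-end claim in the test
suite runs against known ground truth.

**Controlled model correlations.** Representation sets with target pairwise
RDM Spearman correlations (defaults 0.27 between the two models, 0.50 and
0.46 between each model and behavior, the structure of a decorrelated
two-model stimulus set) are built from a shared latent condition embedding
plus independent per-set distortion. Under independent distortions the
pairwise RDM correlation factorizes into the product of the two sets'
latent couplings, so each coupling is solved from the three targets, tuned
by bisection against the measured RDM correlation, and the construction is
re-drawn until all three measured values are within tolerance (default
±0.05). The latent dimensionality defaults to 16, the hidden-layer width
of typical recurrent video-model embeddings.

**Planted pattern datasets.** Three design decisions matter here, all
consequences of making the declared ground truth hold *under the pipeline's
own measurement model*:

1. *Centered, balanced embedding.* Voxelwise standardization centers each
   voxel across conditions, which confines the measurable geometry to the
   double-centered subspace of similarity space — no pattern matrix can
   realize a full-rank correlation structure after z-scoring. The planted
   Gram is therefore double-centered and factorized (negative eigenvalues
   clipped, with the clipped fraction logged per region as the embedding
   distortion), and expressed on an orthonormal voxel basis with zero
   column means and balanced column norms, so that z-scoring is exactly
   transparent to the noiseless signal. Planting the raw Gram instead
   would give every subject an identical systematic distortion, which a
   group test at n = 25 reliably misreads as signal.
2. *Ground-truth consistency for absent components.* Even the centered
   blend generically retains a small nonzero semi-partial rank correlation
   with a component declared absent (weight 0). Declaring "B contributes
   nothing" while planting geometry with nonzero B-unique rank variance
   would make the generator's ground truth false, so the blend is
   iteratively corrected — each zero-weight component's residual rank
   direction is removed by root-finding until its semi-partial is zero —
   before embedding.
3. *Inter-subject variability.* Each subject's regional Gram is a mixture
   `(1 − j)·blend + j·(subject-specific random geometry)` with
   `subject_jitter` j = 0.7 by default, yielding subject-to-group RDM
   correlations around 0.3–0.4, in the range of empirical inter-subject
   consistency of representational geometries, while leaving
   within-subject reliability (and hence noise ceilings) high. Without
   inter-subject variability the sign-flip test's exchangeability premise
   is degenerate: subject statistics differ only by measurement noise, and
   any common artifact, however small, is declared significant.

Independent Gaussian noise of standard deviation `sigma` (default 1,
relative to unit per-voxel signal variance) is added per subject and
repeat; voxels outside planted regions receive pure noise. Windowed
datasets share each subject's idiosyncratic geometry and projection basis
across windows (a subject's "voxels" carry the evolving geometry), with
window-specific blend weights; the default schedules contrast a
rise-and-fall component with a gradually increasing one. All generators
are bit-reproducible under a seed.

**What the generator does not emulate.** Spatial noise correlation,
hemodynamic temporal structure, scanner drift, subject motion, anatomical
variability in region location, and non-Gaussian noise are all absent.
Passing recovery tests therefore demonstrates the pipeline's statistical
logic — valid nulls, calibrated inference, recoverable planted effects —
not robustness to every artifact of real acquisitions.

# Numerical choices

- RDM validity: symmetry and zero diagonal within 1e-8; dissimilarities
  outside `[0, 2]` beyond 1e-9 are an error (they indicate a
  non-correlation-distance input); tiny negative values from float
  round-off are clamped to 0.
- Vectorization order: row-major strictly-upper triangle, one documented
  canonical order so permutation tests and oracles agree bit for bit; the
  round trip through `rdm_from_vector()` is exact.
- Zero-variance voxels are excluded from normalization with a warning, and
  voxels with undefined split-half correlation are excluded from
  reliability masks; zero-variance condition patterns and constant RDM
  vectors are hard errors naming the offending condition.
- Permutation p-values include the observed statistic in the null count;
  exhaustive enumeration is used whenever `2^n` fits in the requested
  permutation count, making small-n p-values exact and seed-independent.
- The Spearman–Brown correction is undefined at r = −1 and returns `NA`
  with a warning there.
- Top-percent ROI ties are broken by lexicographic voxel order;
  `ceiling(pct·n)` guarantees a non-empty ROI for any non-empty parcel.
- Monte-Carlo seeds are derived deterministically from the user seed and a
  cell index, so every group-test cell has an independent, reproducible
  stream and reruns are bit-identical.

# Validation scale

The test suite validates the statistics against independent brute-force
oracles (rank-regression semi-partials to 1e-12 on 100 random instances;
explicit sums-of-squares ANOVA decomposition to 1e-10; exhaustive lattice
enumeration for searchlight geometry) and the full pipeline against
planted ground truth at study scale: 25 subjects, 50 conditions, 5
repeats, a 20³ grid with a brain-like spherical analysis mask for
variance-partition recovery (20 seeded simulated experiments per
condition); 25 subjects, 40 conditions for time-resolved interaction
recovery (50 runs); 12 subjects, 20 conditions for the null calibration of
the interaction test (150 runs) — sizes chosen to exercise the study
design while keeping the suite practical to run routinely.

# Known limitations

- Only correlation-distance RDMs and Spearman RSA are implemented — no
  crossnobis or Mahalanobis dissimilarities, no Kendall's tau-a, no
  whitened RDM comparison.
- Inference is sign-flip permutation plus BH-FDR; no cluster-extent or
  TFCE correction for searchlight maps.
- The semi-partial statistic removes only the *linear-in-ranks* component
  of the controls from the predictor; nonlinear shared structure is
  attributed to the predictor. This is a property of the method itself and
  the reason the generator's ground-truth correction (above) exists.
- The rank-based semi-partial's sampling distribution is not derived
  analytically anywhere in the pipeline; all inference on it is
  permutation-based.
- GLM beta estimation, preprocessing, smoothing, and surface-based
  analysis are upstream and out of scope; the pipeline consumes beta
  images or matrices.
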