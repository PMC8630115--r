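---
title: "Methods: single-cell chromatin scoring and tissue architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell chromatin scoring and tissue architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
defaults are what they are, and what the synthetic-data tests do and do
not demonstrate about real tissue images.

## The pipeline and its assumptions

The pipeline assumes a single-channel image of a DNA stain in which
nuclear intensity reflects local chromatin compaction, with a known pixel
size in micrometres. Stages: intensity normalization → instance
segmentation → per-nucleus feature extraction → quality control →
supervised scoring → pseudo-trajectory → tissue architecture. Every stage
is a pure function of its inputs plus a seed, so reruns are byte-identical
(`run_pipeline()` additionally checksums stage outputs and skips stages
that are current).

Nuclei inherit the clinical annotation of their tissue; there is no
single-cell ground truth in cohorts of this kind. This is deliberate label
noise: a "cancer"-labelled tissue contains normal stromal and immune
nuclei. Classifier accuracies must be read with that in mind, and the
tissue-level majority vote exists precisely because the per-nucleus labels
are noisy.

## Segmentation

The classical intensity path: Gaussian blur (`sigma`, default 2 px), Otsu
threshold, binary median filter (default 3×3; implemented as a majority
vote, which is the exact median on a binary image), Euclidean distance
transform, and watershed seeded from h-maxima of the distance map
(`hmax`, default 2 px). The h-maxima tolerance is what keeps slightly
rough disks from over-segmenting; lowering it splits more aggressively.
Instances are 4-connected; watershed ridge pixels are assigned to
background so instances never touch. Instances touching the image border
are kept but flagged (`touches_border`) — the QC stage, not the
segmenter, decides what to discard. For very small images the blur sigma
is capped so the Gaussian kernel fits inside the image.

Model-based (CNN) segmentation is intentionally out of scope;
`read_label_mask()` imports externally produced instance masks into the
identical downstream path.

## Feature extraction

All intensity-derived features use only in-mask pixels, linearly rescaled
per nucleus to 0–255. This makes features invariant to affine intensity
changes (illumination, exposure) and gives the QC thresholds a fixed
scale; the cost is that a uniform amplitude change of chromatin texture
inside one nucleus is absorbed by the rescale (see the texture-knob note
below).

Boundary curvature: the contour is resampled at 200 equal-arc points and
smoothed with a circular Gaussian of σ = 5 points before finite-difference
curvature. Five points of 200 is 2.5% of the perimeter — strong enough
that the staircase ripple of a rasterized convex shape never produces
spurious negative curvature (verified for disks of r = 20–30 px and a
22×11 ellipse), while a genuine concave wedge is still detected. The
mean curvature of a disk stays within 5% of 1/r at this setting; raising
σ further biases it upward. Relative concavity is computed by pixel
counting (pixels inside the convex hull of the mask's pixel centres vs
mask pixels), which makes the convex baseline exactly zero instead of
drifting with rasterization.

Caliper (Feret) diameters use the convex hull of pixel *corner* points
(the Minkowski sum of the centre hull with the unit pixel), so a 10-pixel
square measures exactly 10√2 across its diagonal and 10 across its side.

The heterochromatin/euchromatin ratio uses a per-nucleus Otsu split of
the 256-bin histogram — parameter-free, at the cost of being meaningless
for unimodal nuclei (a constant nucleus reports 0 with the degenerate
path). The peripheral distribution index is defined as the
intensity-weighted mean squared radial distance over the unweighted one:
1 for uniform staining, above 1 for peripheral enrichment. Hu moments are
computed on the masked intensity (not the binary mask) and signed-log
transformed, sign(h)·log10(|h| + 1e-30), purely for numerical range.

GLCM texture: symmetric co-occurrence matrices at distances
{1, 3, 5, 11, 21} px pooled over the four offset angles, 64 gray levels,
counting only pixel pairs with both ends inside the mask. The distance
set spans sub-focus to whole-nucleus length scales; the level count
trades histogram occupancy against quantization loss and is configurable.
The implementation is vectorized but defined to be bit-equal to a literal
double loop over pixel pairs, and the test suite enforces that equality
at 1e-10 on random crops.

Quality control keeps nuclei with area 2–300 µm², median intensity ≥ 10
and intensity SD ≥ 2 (0–255 scale). The median and SD rules are both read
as lower bounds — "at least" — which matches their purpose of removing
out-of-focus and empty detections; all four thresholds are arguments.

## Scoring and the MGS

Features are standardized, projected on up to 50 principal components
(capped at the rank bound, with the achieved explained variance stored on
the model), and classified by LDA, a random forest (2000 trees, depth 7)
or a two-hidden-layer perceptron (64/32 units, ReLU, Adam, early stopping
on a held-out 15% of the training data). LDA is the reference model: it
is deterministic, interpretable, and its discriminant defines the MGS.
A near-singular within-class covariance falls back to a ridge-regularized
fit (1e-4) with a warning.

The MGS sign is fixed at scoring time so that the normal-like class mean
projects higher; the score is therefore invariant to affine rescaling of
any raw feature (absorbed by standardization) and deterministic given the
model. Train/test splits and cross-validation folds are stratified by
*tissue*, never by nucleus — nuclei of one tissue are strongly correlated,
and splitting within a tissue would leak.

Multi-class ROC AUC is one-vs-rest, macro-averaged. Tissue-level
prediction is the modal predicted nuclear class; ties break toward the
tied class with the higher mean score and are flagged.

## Pseudo-trajectory

The diffusion map uses a Gaussian kernel (default width 0.8 on
discriminant coordinates, matching the scale of standardized LDA scores;
a median-kNN-distance heuristic is available via `sigma = "heuristic"`),
anisotropic density normalization (α = 1) to remove sampling-density
bias, and row normalization to a Markov matrix. Eigenvectors come from
the symmetric conjugate matrix, so the solver is deterministic; each
component's sign is fixed by making its largest-magnitude entry positive.
Components are scaled by their eigenvalues.

Branch assignment is a deliberately simple tip-based scheme, not a
re-implementation of diffusion-pseudotime branching: tips are mutual
extrema of geodesic distance on the weighted k-NN graph of the input
coordinates (first tip farthest from the graph medoid, then maximin), and
each nucleus joins the branch of its graph-nearest tip. Geodesic rather
than embedded distances are used because the spectral embedding can
compress a branch into a tight cluster while the graph retains its
connectivity. Disconnected graph components are assigned per component
with a warning. Branches are named by their dominant stage composition
when stages are supplied. Only nuclei the classifier predicted correctly
(up to 200 per stage, seeded) enter the embedding, which keeps the
trajectory from being shaped by label noise.

## Tissue architecture

Orientation is axial — θ and θ+180° are the same direction — so the
angle difference is min(|Δθ|, 180−|Δθ|) ∈ [0°, 90°]. DBSCAN runs on the
combined metric d² = Δx² + Δy² + (w·Δθ)² with ε = 400 px and a minimum
cluster size of 15. The angle weight w converts degrees to pixels and
defaults to ε/90: two nuclei at right angles are then never neighbours
regardless of distance, while w → 0 recovers position-only clustering.
Whether the original analysis scaled angles at all is unknowable, so w is
a first-class knob. `parameter_scan()` reproduces the diagnostics that
motivate these defaults (median kth-NN distance and angle difference vs
k, cluster count vs ε).

Density features: neighbour counts at radii {5, 15, 25, 40, 50} µm (self
excluded), kth-NN distances for k ∈ {1, 3, 5, 10, 20}, and Voronoi cell
area/perimeter/eccentricity. Voronoi cells are computed exactly by
half-plane clipping against every other point, clipped to a frame (the
convex hull of the centroids dilated by the median nearest-neighbour
distance, or a user frame); cells touching the frame are flagged, since
their geometry reflects the frame, not the tissue.

Cell regions for biomarker calling grow each nucleus by up to 5 µm of
Euclidean distance, stopping at the midline between nuclei (ties to the
lower label). The implementation runs one exact distance transform per
nucleus with a running argmin, and the tests pin it to a per-pixel
brute-force nearest-nucleus assignment. Biomarker positivity is the mean
marker intensity over the cell region against a fixed or Otsu-derived
threshold.

The tissue-level classifier summarizes each architecture feature (± MGS)
per tissue by mean, SD, skewness and kurtosis, projects the summaries on
principal components when they outnumber training tissues, and fits LDA
with a tissue-level split.

## The synthetic generator

Nuclei are ellipses with a low-order Fourier radial perturbation (orders
3–8; bounded amplitude so the boundary cannot self-intersect), filled
with a background intensity plus 2-D Gaussian heterochromatin-like foci
and Poisson-like noise (Gaussian with intensity-proportional SD). Tissue
fields place nuclei by rejection sampling of non-overlapping bounding
circles; layouts can plant co-oriented clusters, lattices, or a DCIS-like
duct (dense, randomly oriented, low-MGS core inside a co-oriented,
high-MGS stromal ring). Stage effects move generator knobs along a cancer
axis — more boundary irregularity, dimmer chromatin, smoother texture for
higher malignancy — and a feature-level cohort generator plants the same
directions (higher concavity and negative-curvature SD, lower median
intensity, lower GLCM entropy/dissimilarity, higher homogeneity) with a
per-nucleus severity whose negative is the planted health axis.

One subtlety the generator exposed: because intensity features are
per-nucleus rescaled, a pure focus-amplitude knob largely cancels out of
the texture statistics. The "chromatin contrast" knob
(`chromatin_texture_knobs()`) therefore raises granularity — more and
sharper foci at fixed amplitude — which genuinely increases GLCM contrast
and decreases homogeneity, the opposition seen between condensed and
decondensed chromatin states.

What the generator does *not* emulate: staining variability, out-of-focus
blur gradients, overlapping nuclei in 3-D projection, anisotropic pixel
sizes, imaging artefacts, and any real biological covariance between
features. Passing tests therefore demonstrate algorithmic correctness and
recovery of planted structure, not clinical performance; the original
patient-cohort accuracies cannot be reproduced without the proprietary
images.

## Numerical choices and degenerate inputs

* Coordinates are 0-based, x = column, y = row; angles counter-clockwise
  from +x; orientations axial in [0°, 180°).
* Masks under 3 pixels yield all-NA features with a `degenerate` flag;
  missing GLCM distances are NA, never dropped.
* A constant image cannot be normalized (error); an empty segmentation
  foreground returns an all-zero mask with a warning.
* LDA ridge 1e-4; eigenvector sign convention as above; DBSCAN noise
  label −1; majority-vote ties logged.
* Problem sizes in the test suite and acceptance script — 8×8 oracle
  crops, 200-disk fields at 1200² px, cohorts of 1000 nuclei across 10
  tissues, 200-point embeddings — were chosen as the smallest sizes at
  which each property is stable across seeds; the whole suite runs in
  about a minute.

## Known limitations

* Branch detection is an approximation; metastable-state analysis and
  full diffusion pseudotime are out of scope.
* The DBSCAN distance matrix is dense (O(n²) memory), fine for
  per-tissue nucleus counts (hundreds to a few thousand) but not for
  whole-slide millions.
* Perimeter and curvature are measured on the smoothed contour, so very
  small nuclei (under ~6 px diameter) have biased boundary features —
  the QC area filter removes most of these anyway.
* H&E input is supported only as generic grayscale after user-side
  conversion; no colour deconvolution.
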