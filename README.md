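# chromatinMGS

Imaging-based single-cell chromatin biomarkers for tissue sections.

Pathologists grade tumours partly by eye, from the shape of nuclei and the
texture of their chromatin. `chromatinMGS` turns that intuition into
numbers: given DNA-stained (Hoechst/DAPI-like) tissue images it segments
every nucleus, quantifies its morphology and chromatin organization,
summarizes each nucleus in a single interpretable **Mechano-Genomic Score
(MGS)**, orders nuclei along a pseudo-trajectory of chromatin
reorganization, and maps orientationally coupled neighbourhoods — regions
where elongated nuclei point the same way because they share local tissue
tension. It is written for image-analysis and computational-pathology
researchers who want a transparent, fully classical (non-CNN) pipeline
whose every stage is testable on synthetic images with known ground truth.

## The score at its core

Per nucleus, four families of features are extracted:

* **global morphology** — area, perimeter, aspect ratio, eccentricity,
  min/max caliper (Feret) diameters;
* **boundary** — signed curvature κ(s) along the arc-length-resampled
  contour (fractions of perimeter with κ > 0 / κ < 0, SD of negative
  curvature), relative concavity (A_hull − A)/A_hull;
* **global intensity** — mean, median, SD, mode, histogram entropy and
  the heterochromatin/euchromatin pixel ratio at the per-nucleus Otsu
  split, all on a per-nucleus 0–255 scale;
* **intensity distribution** — peripheral distribution index
  PDI = (Σ I_i d_i² / Σ I_i)/(Σ d_i² / N), centre-of-mass–centroid
  separation, Hu's seven moment invariants, and gray-level co-occurrence
  (Haralick) statistics — contrast, homogeneity, dissimilarity, entropy,
  ASM, correlation — at several pixel length scales d.

A PCA–LDA classifier is fitted on the standardized features (up to 50
components) to separate normal-like from invasive-like nuclei. The MGS of
nucleus *i* is its signed projection on the linear discriminant **w**:

    MGS_i = s · wᵀ z_i ,   s ∈ {−1, +1} chosen so normal-class mean is higher

so a high MGS reads as "healthy, normal-like chromatin". Downstream, the
discriminant coordinates feed a diffusion map (Gaussian kernel, width
σ = 0.8, density-normalized Markov transition matrix) whose leading
components order nuclei along cancer progression, with branches assigned
from geodesic tip points on a k-NN graph. Tissue architecture is read from
nuclear positions and axial orientations: DBSCAN with the combined metric
d² = Δx² + Δy² + (w·Δθ_axial)² (ε = 400 px, minimum 15 nuclei) finds
orientationally coupled regions, and local density is quantified by
neighbour counts at 5–50 µm, kth-nearest-neighbour distances
(k = 1…20) and exact clipped Voronoi cell geometry.

## Worked example

Everything below runs on synthetic tissue images generated by the package
itself — no external data needed.

```r
library(chromatinMGS)

# 6 synthetic tissues (3 normal, 3 invasive), 40 nuclei each
cohort <- generate_cohort(stages = c("normal", "invasive"),
                          n_tissues = 3, n_nuclei = 40,
                          width = 448, height = 448, seed = 1)

rows <- list()
for (tid in names(cohort$tissues)) {
  ti   <- cohort$tissues[[tid]]
  img  <- normalize_image(ti$image)
  mask <- segment_nuclei(img)                    # Otsu + watershed
  crops <- crop_nuclei(img, mask, tissue_id = tid)
  rows[[tid]] <- feature_table(crops, stage = ti$stage)
}
tab <- qc_filter(do.call(rbind, rows))           # area 2-300 um^2, etc.

sp    <- split_train_test(tab, seed = 1)         # split by tissue
model <- fit_classifier(sp$train, "lda")
pred  <- predict_nuclei(model, sp$test)
balanced_accuracy(sp$test$stage, pred$class)
tab$mgs <- compute_mgs(model, tab, normal_class = "normal")
aggregate(mgs ~ stage, tab, mean)
```

Output:

```
<scoring_model> LDA on 25 PCs (100.0% variance), classes: invasive, normal
held-out balanced accuracy: 1
     stage       mgs
1 invasive -17.37421
2   normal  18.12034
```

240 nuclei pass QC; the held-out tissues classify perfectly because the
generator plants a strong malignancy effect (irregular boundaries, dimmer
and smoother chromatin for the invasive stage), and the MGS separates the
two populations in the documented direction — normal high, invasive low.
`mgs_feature_correlations(tab, tab$mgs)` then ranks which features carry
the score (here intensity and boundary-convexity features top the list).

A command-line front end wrapping the same functions is in
`inst/cli/chromatin-mgs.R`
(`Rscript inst/cli/chromatin-mgs.R simulate|segment|features|qc|run ...`),
and `run_pipeline()` orchestrates the whole chain with checksummed,
resumable, byte-reproducible stage outputs.

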