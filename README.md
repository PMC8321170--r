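# petsurf

Fully 3D segmentation of tumor volumes on PET images, for researchers in
quantitative nuclear-medicine imaging who need operator-independent
biological tumor volumes (BTVs) for treatment planning or radiomics.
Instead of delineating each PET slice independently and stacking the
contours, `petsurf` evolves a single closed surface through the whole
image stack, so cross-slice information drives the result and the
surface can split or merge freely (disjoint lesions, holes).

## The model

The surface *S* is the zero level set of a signed-distance field φ
(negative inside).  It moves to minimize a localized region energy with
a machine-learning prior:

```
E = ∫_S  λ ( ∫_{R_in}  χ_l(x,s) · P̄_out(x) dx  +  ∫_{R_out} χ_l(x,s) · P̄_in(x) dx )
       + (1−λ) ( ∫_{R_in}  χ_l(x,s) (SUV(x) − u_l(s))² dx
               + ∫_{R_out} χ_l(x,s) (SUV(x) − v_l(s))² dx )  dS
```

where χ_l(x,s) selects the ball of radius *l* voxels around each surface
point, u_l and v_l are the local interior/exterior mean uptakes, and
P̄_in / P̄_out are the local mean verdicts of a three-class tissue
classifier: a linear discriminant (regularized pooled covariance)
trained on 3×3×3 voxel windows labelled lesion (≥ 18 of 27 voxels inside
the reference mask), border-line (1–17), or background (0).  The prior
penalizes interior voxels locally classified as background and exterior
voxels locally classified as lesion; border-line tissue is neutral, so
the classifier never fights the data term at the boundary it cannot
resolve.  Defaults: λ = 0.01, l = 3 voxels, plus a curvature
regularization (weight α = 0.2) for stability on noisy data.

No artificial stop condition is imposed: iteration ends when the sign
pattern of φ is stable (the fraction of narrow-band voxels changing sign
stays below 10⁻⁴ for 30 consecutive iterations).

Because clinical PET volumes cannot ship with a package, `petsurf`
includes a phantom generator (sphere, ellipsoid, bilobed, torus,
disjoint blobs on an anisotropic grid, with PSF blur and noise) whose
exact gold-standard masks make every stage testable, and an evaluation
suite (sensitivity, specificity, PPV, accuracy, Dice, Hausdorff
distance, Pearson correlation).

## Worked example

```r
library(petsurf)

# self-contained run: default 64×64×48 sphere phantom, 8:1 contrast,
# 5% noise, 5 mm PSF; trains the classifier on a separate phantom
cfg <- run_config(phantom = phantom_spec(), seed = 11)
res <- run_pipeline(cfg, "run1", verbose = TRUE)

res$report$classifier$cv_mean$accuracy   # 0.9969  (5-fold CV, window samples)
res$report$segmentation$rates$dsc        # 0.9962  (Dice vs gold mask)
res$report$segmentation$hd               # 1       (Hausdorff, voxels)
res$report$converged                     # TRUE    (110 iterations)
```

The run directory holds every intermediate artifact: the phantom and
gold mask, the serialized classifier (`model.json`, reusable across
segmentations), the converged BTV mask, the per-iteration energy and
sign-flip history, and a JSON report.  Identical config + seed gives
byte-identical outputs.

The same stages are scriptable individually (see the `phantom`,
`sample`, `train`, `segment`, `evaluate`, `run` subcommands of
`inst/scripts/petsurf`), e.g.:

```sh
petsurf phantom --shape bilobed --grid 32,32,24 --noise 0.2 \
        --out-vol v.nii.gz --out-mask g.nii.gz
petsurf segment --vol v.nii.gz --model m.json --roi g.nii.gz --out pred.nii.gz
petsurf evaluate --pred pred.nii.gz --gold g.nii.gz --out rep.json
# DSC 0.9995, HD 1.000 voxel -> rep.json
```

For real data, point `run_config()` at NIfTI paths (`volume`, `gold` or
a pretrained `model`, and an ROI mask or `roi_box`); activity images
convert to standardized uptake values with `to_suv()`.

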