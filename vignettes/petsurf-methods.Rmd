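---
title: "Active-surface PET segmentation with a tissue-classification prior: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active-surface PET segmentation with a tissue-classification prior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petsurf)
```

## The problem and the model

Delineating a biological tumor volume (BTV) on PET is hard because the
tracer signal falls off smoothly (scanner point-spread function,
partial-volume effects) and slice spacing usually exceeds in-plane
resolution, so slice-by-slice contouring both ignores cross-slice
structure and inherits a preferential direction.  `petsurf` treats the
delineation as the evolution of one closed surface embedded in the full
3D volume: the surface is the zero level set of a signed-distance field
φ (negative inside), which makes splits, merges and holes automatic.

The energy the surface minimizes combines two ingredients, evaluated in
spherical neighborhoods of radius `l` voxels around each surface point:

* a **localized region term** comparing each neighborhood voxel's
  standardized uptake value (SUV) against the local interior mean
  `u_l` or exterior mean `v_l` — localized, because tumors sit on
  heterogeneous backgrounds where global region statistics mislead;
* a **classification prior**: a three-class linear discriminant,
  trained on 3×3×3 voxel windows, labels tissue as lesion, border-line
  or background; interior voxels whose neighborhood is locally
  classified background are penalized, as are exterior voxels locally
  classified lesion.  Border-line tissue — windows straddling the
  reference boundary — contributes no penalty in either direction, so
  the prior is deliberately silent exactly where it is least reliable.

The prior's weight is λ (default 0.01, so the data term dominates and
the classifier acts as a tie-breaker in ambiguous territory), and the
neighborhood radius is `l = 3` voxels, matching the classifier's window
scale.  Neighborhoods are spheres in index space; on anisotropic grids
this matches the window convention of the classifier rather than
physical isotropy, which is the consistent choice given that both
features and prior live on the voxel lattice.

### Labelling rule

A 27-voxel window is **background** when no voxel lies in the reference
mask, **border-line** with 1–17 reference voxels, and **lesion** with
18–27.  The asymmetric split (17/18 rather than 13/14) makes the lesion
class conservative: a window is only "lesion" when two thirds of it is
tumor.

### The classifier

Linear discriminant analysis with one pooled covariance was chosen as
the simplest member of the discriminant family and the most stable
under the extreme class imbalance window sampling produces (background
windows outnumber lesion windows by orders of magnitude).  The pooled
27×27 covariance is ridge-regularized, `Σ + γI` with
`γ = 10⁻⁶ · tr(Σ)/27` by default, because near-constant background
windows on low-noise data make Σ rank-deficient.  Priors are taken
as fitted (no rebalancing); the discriminant score of class *c* is
`δ_c(v) = vᵀΣ⁻¹μ_c − μ_cᵀΣ⁻¹μ_c/2 + log π_c`.  Training uses a seeded
stratified 80/20 split with held-out metrics attached to the model,
and stratified k-fold cross-validation (default k = 5) is available
separately; fold assignment cycles across classes so every fold is
populated even in leave-one-out use.  Whole-volume classification
applies the linear discriminants as 27-tap linear filters on the
edge-replicated volume, so every voxel receives a label (training
extraction, by contrast, uses interior windows only, keeping the
training set free of padding artifacts).

## Discretization and numerics

* **Surface measure.** The energy integral over the surface is realized
  on the narrow band with a smoothed Dirac delta
  `δ_ε(φ) = (1 + cos(πφ/ε)) / (2ε)` for `|φ| < ε`, `ε = 1.5` voxels.
* **Neighborhood sums** are exact linear convolutions with the discrete
  ball kernel, evaluated by zero-padded FFTs (7-smooth padded sizes);
  at the grid edge the clipped stencil is used, i.e. denominators are
  in-grid counts.  When `l` reaches the grid diameter every
  neighborhood covers the whole grid and the sums collapse to global
  totals; in that limit the flow reduces to the global
  piecewise-constant (Chan–Vese) model, which the tests exploit as an
  exactly solvable case.
* **Descent.** The update velocity is
  `δ_ε(φ)[λ(P̄_out − P̄_in) + (1−λ)((SUV−u_l)² − (SUV−v_l)²)] + α δ_ε(φ) κ`,
  with κ the mean curvature of φ (clamped to ±1/voxel).  A voxel that
  matches the interior statistics, or that the classifier calls lesion,
  gets negative velocity and joins the interior.  Each iteration the
  velocity field is normalized by its maximum so the largest
  displacement is `dt = 0.45` voxel (CFL-safe).
* **Curvature term.** The energy itself carries no smoothness term; the
  explicit discrete flow without one is unstable on noisy data, so a
  curvature regularization with weight α (default 0.2, normalized
  units) is added as an extension.  α = 0 is supported and is used by
  the oracle and monotone-descent tests.
* **Re-distancing.** Every 25 iterations φ is re-distanced by the
  Sussman PDE `φ_t = S(φ₀)(1 − |∇φ|)` (Godunov upwind) with a subcell
  anchor: interface voxels relax toward `φ₀/|∇φ₀|`, and the original
  sign pattern is enforced, so the zero crossing never moves across a
  voxel center.  An axis-aligned planar signed-distance field is an
  exact fixed point of this scheme.
* **Convergence** means a stable sign pattern: the fraction of
  narrow-band voxels changing sign stays below 10⁻⁴ for 30 consecutive
  iterations.  The window deliberately exceeds the re-distancing period
  (25): between re-distancing events the normalized updates steepen φ
  away from moving fronts and locally freeze the flow, so a quiet
  stretch shorter than one cycle can be an artifact — in particular, a
  slowly shrinking remnant blob (e.g. the last few voxels between two
  separating components) pauses for several iterations at a time.
  `max_iter` (default 500) is a safety net and is flagged distinctly
  from convergence.
* **Recorded energy.** The same steepening distorts any surface weight
  computed from φ's magnitudes, deflating the measured energy between
  re-distancing events and producing spurious jumps after them.  The
  per-iteration history therefore measures the energy density with unit
  weights on the sign-pattern interface (voxels with a face-neighbor
  sign change), a pure function of the evolving region.
  `total_energy()` keeps the δ_ε-weighted functional of the field as
  given — that is the quantity the brute-force oracle in the test suite
  verifies to 10⁻⁹ relative error.
* **Localized means fallback.** If a neighborhood has no interior (or
  no exterior) voxels, that side's mean falls back to the global side
  mean, so the velocity is defined everywhere.

## Initialization

The user input is a rough region of interest.  The hottest voxel inside
the ROI anchors a 26-connected component of
`{vol ≥ frac · max}` (default `frac = 0.4`, the common 40%-of-max PET
practice); the component's voxel centroid and second-moment principal
axes define an ellipsoid with semi-axes `scale · sqrt(eigenvalues)`
(default `scale = 2.6`; for a solid ellipsoid the exact factor is
`sqrt(5) ≈ 2.24`, so the default envelops the seed with a modest
margin), floored at 2 voxels and grown uniformly until the maximum
voxel is inside.  Degenerate seeds (fewer than 4 voxels, or coplanar)
fall back to a 3-voxel sphere at the centroid.  Moments are computed in
voxel units so the ellipsoid lives on the index grid like φ.  The
ellipsoid is converted to an approximate signed distance and
re-distanced numerically.  The only hard requirement on the
initialization is that it envelops part of the tumor and contains the
maximum-uptake voxel; the evolution does the rest, including topology
changes (a single ellipsoid covering two disjoint lesions splits into
two components).

## The phantom generator

Clinical PET volumes cannot ship with the package, so every stage is
exercised on synthetic phantoms: a bright tumor support (sphere,
ellipsoid, bilobed, torus, or two disjoint blobs, defined in world mm
on the default anisotropic 2.73 × 2.73 × 3.27 mm grid) over a dim
background, blurred by an isotropic Gaussian PSF specified in world mm,
plus additive Gaussian noise (a Poisson option exists).  Defaults —
64 × 64 × 48 grid, tumor uptake 8 vs background 1 (a high-contrast
FDG-avid lesion), noise sd 0.4 (5% of the tumor level), PSF FWHM 5 mm
(typical clinical PET resolution), 24 mm sphere radius (a large lesion)
— are the package's standing study conditions.  The gold mask is the
exact voxel-center-in-shape support, with no partial-volume
antialiasing: partial volume enters only through the PSF applied to the
intensity image, which keeps the reference unambiguous.  The default
grid is desk-scale (a clinical 256 × 256 matrix is supported but not
default) so the full suite runs in minutes.

What the phantoms do **not** emulate: scatter and attenuation,
reconstruction artifacts, spatially varying noise, heterogeneous tumor
uptake, and physiological uptake structures near the lesion.  Passing
the phantom suite therefore demonstrates the correctness and stability
of the machinery — exact recovery in noiseless limits, robustness at 5%
noise, topology handling — not clinical-grade accuracy; on real data
the classifier and the prior term must carry far more of the burden.

## Evaluation suite

Sensitivity, specificity, positive predictive value, accuracy and Dice
are computed from voxelwise confusion counts; a 0/0 rate (empty
positive set) is defined as 1.0 and flagged, so degenerate sweeps do
not crash.  The Hausdorff distance is computed between boundary voxel
sets (mask voxels with a face-adjacent background voxel) — equivalent
to the solid-set boundary distance and far cheaper — in voxel units by
default, with a per-axis mm mode.  Pearson correlation for paired
per-case score lists delegates to `stats::cor`.  Topology checks use
the exact Euler characteristic of the voxel solid's cubical complex
(`V − E + F − C`; 1 for a ball, 0 for a solid torus, additive over
components), which equals the boundary-mesh computation for
handlebodies (`χ = 1 − genus`).

## Known limitations and characteristic biases

* The localized prior carries an inward bias of roughly `l²/(4R)` on a
  convex surface of radius R (the tangent ball of a convex body is less
  than half inside it), about 0.3 voxel for R = 8, vanishing for
  well-resolved lesions.  The default curvature weight adds a further
  small shrink bias; both are negligible against the data term at the
  default λ.
* Convergence by sign-pattern stability can coexist with sub-voxel
  creep of the continuous interface; the reported mask is the voxelized
  region, so this is invisible at mask level.
* One surface, one label: multi-lesion segmentation works only when all
  lesions are inside one ROI/initialization basin; multi-phase level
  sets are out of scope.
* SUV conversion is body-weight SUV (`activity · weight / dose`) and
  assumes decay-corrected input.

## Problem sizes in the shipped tests

Module tests run on 9³–24³ grids against brute-force oracles; the
end-to-end checks use the default 64 × 64 × 48 phantom and 48 × 48 × 36
topology phantoms (noiseless, PSF-free — topology handling, not noise
robustness, is what those exercise), chosen so the whole suite and the
acceptance script each complete in minutes on one core while keeping
the default study conditions intact.
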