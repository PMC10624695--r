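---
title: "Methods: wavelet scattering features and affine PCA classification for OCT images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet scattering features and affine PCA classification for OCT images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`octscatter` classifies grayscale images — retinal OCT B-scans in the
intended application — by (1) mapping each image to a two-layer wavelet
scattering vector and (2) assigning it to the nearest per-class affine PCA
subspace. This vignette records the model, its assumptions, the numerical
choices behind the implementation, and what the accompanying synthetic
data generator does and does not establish.

## The scattering transform

Let $f$ be an $H \times W$ image with intensities in $[0,1]$. With the
isotropic Gaussian $\phi(x) = \frac{1}{2\pi\sigma^2}
e^{-|x|^2/2\sigma^2}$ and its dilation $\phi_J(x) = 2^{-2J}\phi(2^{-J}x)$,
the Morlet wavelet is

$$\psi(x) = c_1\,(e^{i\xi\cdot x} - c_2)\,\phi(x),$$

a plane wave localized by the Gaussian window, with $c_2$ chosen so
$\int \psi = 0$. Scaled and rotated copies
$\psi_{j,\gamma}(x) = 2^{-2j}\psi(2^{-j}R_\gamma x)$ are built for
$j = 0,\dots,J-1$ and $\gamma \in \{k\pi/r\}_{k=0}^{r-1}$. The transform
computes

$$S_{0}f = f \ast \phi_J,\qquad
S_{1}f = |f \ast \psi_{j_1,\gamma_1}| \ast \phi_J,\qquad
S_{2}f = \bigl||f \ast \psi_{j_1,\gamma_1}| \ast \psi_{j_2,\gamma_2}\bigr| \ast \phi_J,$$

each uniformly subsampled with grid step $2^J$, flattened in a fixed
canonical order (order 0; order 1 sorted by $(j_1,\gamma_1)$; order 2 by
$(j_1,\gamma_1,j_2,\gamma_2)$) into a vector of length
$N_J = (1 + rJ + r^2 J(J-1)/2)\,2^{-2J} HW$.

The modulus is the nonlinearity: it is contractive, so together with a
filter bank whose Littlewood–Paley sum is bounded by 1 the whole map is
non-expansive, and averaging the modulus with the wide window $\phi_J$
yields local translation invariance at scales below $2^J$ while keeping
the high-frequency information that plain blurring would destroy.

**Second-layer scale range.** The implementation uses strictly increasing
scales $j_2 > j_1$. Non-increasing second-layer paths carry almost no
energy (the first modulus moves content toward lower frequencies), and
only the increasing-scale convention is consistent with the path count
$r^2 J(J-1)/2$ in $N_J$. A flag (`include_equal_scales`) adds the
$j_2 = j_1$ paths for sensitivity analyses.

**Energy accounting.** `energy_capture()` reports
$E_{012}/(E_{012}+E_3)$, where $E_{012}$ sums the squared norms of all
order-0/1/2 outputs before subsampling and $E_3$ sums the squared norms of
the order-3 internal modulus signals $\bigl|\,||f\ast\psi|\ast\psi|\ast\psi_{j_3,\gamma_3}\bigr|$
over increasing-scale paths — the energy that would feed a third layer.
The acceptance script measures this fraction on synthetic B-scans; the
two-layer truncation is justified when it is near 1.

## Numerical construction of the filter bank

* **Sampling convention.** All filters live on the same $(H,W)$ grid as
  the (padded) image, in the wrapped discrete layout with the phase
  reference at index $(1,1)$ and negative coordinates wrapped to the upper
  half of each axis. Frequency-domain convolution is then a pure pointwise
  product; no shifts are needed at use time.
* **Discrete zero mean.** $c_2$ is computed from the *sampled* grids as
  the ratio of the windowed plane-wave sum to the window sum, so each
  band-pass filter's DC response vanishes exactly (to rounding), not just
  in the continuous limit. At $\sigma = 0.85$ the sampled $c_2$ differs
  from the continuous closed form $e^{-\sigma^2|\xi|^2/2} \approx 0.1346$
  by a small aliasing correction (a few percent); the tests check both.
* **Frequency orientation.** The plane-wave frequency before rotation is
  $\xi = (3\pi/4, 0)$ — modulus $3\pi/4$ along the first axis, the
  standard Morlet construction; rotation of the argument by $R_\gamma$
  rotates the passband accordingly. Only $[0,\pi)$ is covered because
  angles differing by $\pi$ give conjugate filters.
* **Littlewood–Paley normalization.** All band-pass filters are scaled by
  one common constant, the largest for which
  $A(\omega) = |\hat\phi_J|^2 + \tfrac12\sum_{j,\gamma}(|\hat\psi_{j,\gamma}(\omega)|^2 + |\hat\psi_{j,\gamma}(-\omega)|^2) \le 1$
  everywhere; the supremum 1 is attained (at DC, where $A = 1$ by
  construction). This makes the transform non-expansive and the energy
  fraction meaningful. The frame is deliberately not tight: with
  $\sigma = 0.85$ the infimum of $A$ sits around 0.27 for a $J = 3$,
  $r = 8$ bank on a $128^2$ grid, with the dip at the transition between
  $\phi_J$ and the coarsest wavelet ring; the test suite pins this as a
  regression value. A per-filter (tight-frame) normalization was rejected
  because it changes the relative weighting of scales that the single
  $c_1$ convention preserves.
* **Boundary handling.** B-scans are not periodic, so each image is
  reflection-padded to the next multiple of $2^J$ per dimension and the
  convolutions are circular on the padded grid; outputs are cropped back.
  For image sides already divisible by $2^J$ (all test fixtures) this is a
  no-op and the transform is exactly circular.
* **Subsampling.** Outputs are sampled at stride $2^J$ starting at the
  first grid point. Intermediate modulus fields are kept at full
  resolution; the cost is modest at the image sizes involved and removes
  any subsampling-induced error inside the cascade.

## The classifier

Class $k$ with training vectors $x_1,\dots,x_{n_k}$ is summarized by the
sample mean $\bar x_k$ and the top-$d_k$ right singular vectors of the
centered row matrix, $d_k = \min(d, n_k - 1, N_J)$ further truncated at
the numerical rank (singular values below $10^{-10}$ of the largest are
treated as zero). The SVD-of-rows route is used throughout — the
$N_J \times N_J$ covariance is never formed, which keeps the cost at
$O(n_k^2 N_J)$ instead of $O(N_J^3)$. Prediction minimizes the residual of
the orthogonal projection onto $\bar x_k + \mathrm{span}(V_{d,k})$; the
residual is computed as the norm of the explicitly deflated vector
$w - V(V^\top w)$ rather than $\sqrt{\|w\|^2 - \|V^\top w\|^2}$, avoiding
catastrophic cancellation for points near a subspace.

Deliberate conventions where the design was open: per-class (not pooled)
covariances, matching the affine-space definition; covariance centering
with divisor $n_k - 1$ (only directions matter, but the divisor documents
the estimator); no feature standardization or whitening (the classifier
operates on raw scattering coefficients); prediction ties broken toward
the smallest class index in sorted-label order; eigenvector signs fixed by
making the largest-magnitude entry positive, so fits are bit-reproducible.
A class with a single (or fully duplicated) training sample degenerates to
distance-to-mean classification rather than failing.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `sigma` | 0.85 px | Gaussian envelope width; sets the bandwidth of every filter. |
| `xi` | $(3\pi/4, 0)$ rad/px | Prototype passband center, near but below Nyquist. |
| `r` | 12 | Orientations in $[0,\pi)$; 6–12 are sensible, finer banks mostly help oriented texture. |
| `J` | $\lfloor\log_2 \min(H,W)\rfloor - 1$ | Invariant scale $2^J$ = half the minimum image dimension, rounded down to a power of two; larger $J$ buys invariance at the price of spatial detail. |
| `d` | 30 | Per-class subspace rank; capped automatically at $n_k - 1$. |
| `train_fraction` / `k_folds` | 0.8 / off (10 when used) | Stratified hold-out, or k-fold with pooled confusion. |
| `speckle_sigma` | 0.15 | Generator: multiplicative lognormal speckle scale. |
| `curvature` | 3 px | Generator: sinusoidal warp amplitude of the layer stack. |

The default $J$ follows the half-minimum-dimension rule; an alternative
reading ties $2^J$ to the full minimum dimension, which leaves only a
$1 \times 1$ (or smaller) sampling grid per path and discards all spatial
layout, so the half rule is the default and `J` is always overridable.

## The synthetic generator

`oct_default_specs()` renders five classes of B-scan-like images: stacked
bright/dark horizontal bands with jittered boundaries and a sinusoidal
warp, plus one hallmark lesion per disease class — an intraretinal dark
dome (`dme_like`), a bright sub-band elevation (`amd_like`), a
full-thickness central gap (`hole_like`), a large subretinal dark dome
(`csr_like`) — under multiplicative lognormal speckle
($x \mapsto x\,e^{\sigma z - \sigma^2/2}$), the standard first-order model
for coherent-imaging speckle. Per-image seeds are counter-mixed from the
master seed, so datasets are reproducible image-by-image and no two
derived streams coincide.

What it emulates: the layered geometry, class-distinct focal morphology,
and multiplicative noise that drive scattering features on real OCT. What
it does not: A-scan physics (depth-dependent attenuation, shadowing),
vendor-specific contrast, motion artifacts, anatomical variability, or
patient-level correlation between scans. Consequently, passing the
end-to-end benchmark shows the pipeline is wired correctly and separates
structured texture classes at realistic noise levels — it does not certify
accuracy on any real dataset. Splits are per-image; with real data,
patient-grouped splitting should be used to avoid leakage (the manifest's
`case_id` column exists for this purpose).

## Problem sizes used by the tests

The suite exercises the transform at $16^2$–$128^2$ images with
$J \in \{1,\dots,5\}$ and $r \in \{1,2,4,6,8,12\}$. The end-to-end
benchmark uses 5 classes × 40 images at $64 \times 64$ with $J = 3$,
$r = 8$, $d = 10$; energy capture uses 20 images at $128 \times 128$ with
$J = 3$, $r = 8$. These sizes were chosen so the full pipeline remains a
desk-scale computation in plain R while every scale-dependent code path
(padding, subsampling, multi-scale path enumeration) is exercised.

## Known limitations

* Orders $\ge 3$ exist only inside the energy diagnostic; they are not
  available as features (by design — two layers suffice).
* Rotation-invariant scattering variants and learned filter banks are out
  of scope.
* The macro one-vs-rest AUC is computed from negated projection residuals
  with midrank tie handling; other multiclass AUC conventions exist and
  give different numbers.
* BMP input is not supported (no reader dependency); PNG/TIFF/JPEG are.
* The transform is computed in double precision with R's FFT; exact
  bit-reproducibility across BLAS/FFT implementations is not guaranteed,
  though all documented invariants hold to stated tolerances.
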