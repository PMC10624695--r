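# octscatter

Translation-invariant image features via a two-layer 2D Morlet **wavelet
scattering transform (WST)**, plus a **nearest affine PCA subspace
classifier**, for grayscale retinal OCT B-scans (and any other grayscale
texture-classification task). The pipeline needs no learned filters and
very little training data, which makes it attractive for medical imaging
where labels are scarce: features are fixed wavelet convolutions, and the
classifier is a per-class PCA — the whole model is interpretable and cheap.

For ophthalmic use, the disease classes of interest are the usual OCT
morphologies: diabetic retinopathy / macular edema (thickened layers,
intraretinal fluid), age-related macular degeneration (RPE elevation,
drusen), macular hole, and central serous retinopathy (subretinal fluid).
A seeded synthetic B-scan generator emulating exactly these morphologies is
included, so every part of the pipeline is testable offline.

## The model

**Features.** With the Gaussian window
φ(x) = (2πσ²)⁻¹ exp(−|x|²/2σ²), σ = 0.85, and the zero-mean Morlet wavelet
ψ(x) = c₁(e^{iξ·x} − c₂)φ(x) (|ξ| = 3π/4), scaled/rotated copies
ψ_{j,γ}(x) = 2^{−2j} ψ(2^{−j} R_γ x) are built for dyadic scales
j = 0,…,J−1 and r equidistant angles γ ∈ {kπ/r} in [0, π). The scattering
coefficients of an image f are

- order 0: f ∗ φ_J,
- order 1: |f ∗ ψ_{j₁,γ₁}| ∗ φ_J,
- order 2: ||f ∗ ψ_{j₁,γ₁}| ∗ ψ_{j₂,γ₂}| ∗ φ_J  (j₂ > j₁),

each subsampled on the 2^J grid and flattened into a vector of length
N_J = (1 + rJ + r²J(J−1)/2)·2^{−2J}·N for an N-pixel image. Features are
invariant to translations below the scale 2^J and stable to small
deformations; orders 0–2 capture essentially all of the signal energy
(>98%), which is why the cascade stops at two layers. The band-pass bank
is normalized so the Littlewood–Paley sum has supremum exactly 1, making
the transform non-expansive.

**Classifier.** Each class k is modeled by the affine space
A_{d,k} = E(S_J f_k) + V_{d,k}, where V_{d,k} is spanned by the top-d
principal directions of the class's feature covariance (d = 30 by
default). A sample is assigned to the class minimizing the projection
residual ‖S_J f − P_{A_{d,k}}(S_J f)‖₂.

## Worked example

Five synthetic classes, 20 images each at 64×64, scattering at J = 3 and
r = 8 orientations, rank-10 subspaces, stratified 80/20 split:

```r
library(octscatter)
specs <- oct_default_specs(c(64, 64))
ds  <- generate_dataset(specs, n_per_class = 20, shape = c(64, 64), seed = 1)
cfg <- experiment_config(r = 8, J = 3, d = 10, seed = 1)
ex  <- run_experiment(cfg, ds)
print(ex)
#> Scattering experiment (octscatter 0.1.0)
#>   J = 3, r = 8, sigma = 0.85, d = 10, seed = 1; N_J = 13888
#> Evaluation on 20 samples: accuracy 1.0000, macro OvR AUC 0.9688
#> Confusion matrix (rows = true):
#>            predicted
#> true        amd_like csr_like dme_like hole_like normal
#>   amd_like         4        0        0         0      0
#>   csr_like         0        4        0         0      0
#>   dme_like         0        0        4         0      0
#>   hole_like        0        0        0         4      0
#>   normal           0        0        0         0      4
```

Each image yields 217 scattering paths × an 8×8 subsampled grid = 13,888
features; all 20 held-out scans are classified correctly. The filter bank
itself and its energy behavior:

```r
bank <- build_filter_bank(filter_params(c(64, 64), J = 3, r = 8))
print(bank)
#> Morlet scattering filter bank: 64x64 grid, J = 3, r = 8, sigma = 0.85
#>   24 band-pass filters; Littlewood-Paley sup = 1.000000000, inf = 0.0896
energy_capture(ds$images[[1]], bank)
#> [1] 0.9987082
```

`energy_capture()` reports the fraction of cascade energy retained by
orders 0–2 relative to what would continue into a third layer — here
99.9%, consistent with truncating the network at two layers.

Real datasets are loaded with `load_dataset()` from a per-class image
directory or a `path,label,case_id` manifest CSV (PNG/TIFF/JPEG; optional
anti-aliased resize). A thin command-line wrapper with `generate`,
`features`, `train`, `evaluate` and `run` subcommands is installed at
`inst/cli/octscatter`. Public OCT datasets this pipeline is suited to
(OCTID, the Topcon/Isfahan set, Duke, Heidelberg/Noor) ship as per-class
image folders and can be pointed to directly; they are not downloaded by
the package.

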