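Package: octscatter
Title: Wavelet Scattering Features and Affine PCA Classification for Retinal OCT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-layer two-dimensional Morlet wavelet scattering transform for
    grayscale images, producing translation-invariant, deformation-stable
    feature vectors, together with a nearest affine PCA subspace classifier,
    stratified hold-out and k-fold evaluation tooling, dataset loaders for
    per-class image directories or CSV manifests, and a seeded generator of
    synthetic OCT-like retinal B-scans (layered reflectivity bands, focal
    lesions, multiplicative speckle) so the whole pipeline is testable
    without external data. Filter banks are Littlewood-Paley normalized so
    the transform is non-expansive and the energy captured by scattering
    orders 0-2 is a meaningful fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    tiff,
    jpeg,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
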