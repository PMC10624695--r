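# Run code with a private, restored RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Counter-mixed derived seed: independent, reproducible per-image streams,
# kept below 2^31.
derive_seed <- function(seed, class_index, i) {
  as.integer((as.double(seed) * 48271 + class_index * 10007 + i * 65537) %%
               2147483629) + 1L
}

#' Specification of one synthetic OCT-like image class
#'
#' Describes how to render grayscale B-scan-like images for one class:
#' stacked horizontal reflectivity bands (retinal layers) with per-band mean
#' intensity and thickness, optional per-class structural lesion, a global
#' sinusoidal curvature of the layer stack, boundary jitter, and
#' multiplicative speckle.
#'
#' Lesion types emulate the hallmark OCT findings of the disease classes:
#' `dome_fluid` (a dark dome-shaped fluid pocket, as in macular edema or
#' central serous retinopathy), `band_thickening` (a locally thickened
#' layer, as in edematous retina), `gap` (a full-thickness break in the
#' central layers, as in macular hole), `sub_band_elevation` (a bright
#' dome elevating the bottom band, as in drusen / pigment-epithelium
#' detachment in AMD).
#'
#' @param name class label.
#' @param layer_intensities per-band mean reflectivity in `[0,1]`, top to
#'   bottom.
#' @param layer_thickness per-band mean thickness in pixels (recycled to
#'   the number of bands).
#' @param thickness_jitter s.d. of the per-band thickness perturbation in
#'   pixels (default 1).
#' @param lesion `NULL` or a list with `type` (one of `"dome_fluid"`,
#'   `"band_thickening"`, `"gap"`, `"sub_band_elevation"`), `size` (range
#'   in pixels: radius, added thickness, or half-width depending on type),
#'   `delta` (intensity change in `[-1,1]`), and optionally `depth`
#'   (`"intra"` or `"sub"`, where in the stack a fluid dome sits).
#' @param speckle_sigma multiplicative lognormal speckle scale (default 0.15).
#' @param curvature amplitude in pixels of the sinusoidal vertical warp of
#'   the whole stack (default 3).
#' @param background background reflectivity (default 0.05).
#' @return An object of class `"oct_class_spec"`.
#' @export
synthetic_class_spec <- function(name, layer_intensities, layer_thickness,
                                 thickness_jitter = 1, lesion = NULL,
                                 speckle_sigma = 0.15, curvature = 3,
                                 background = 0.05) {
  if (!nzchar(name)) stop("class name must be nonempty")
  if (any(layer_intensities < 0 | layer_intensities > 1))
    stop("layer intensities must lie in [0,1]")
  n <- length(layer_intensities)
  layer_thickness <- rep_len(layer_thickness, n)
  if (any(layer_thickness < 1)) stop("layer thickness must be >= 1 pixel")
  if (!is.null(lesion)) {
    if (!lesion$type %in% c("dome_fluid", "band_thickening", "gap",
                            "sub_band_elevation"))
      stop("unknown lesion type")
    lesion$size <- rep_len(lesion$size, 2L)
    if (is.null(lesion$depth)) lesion$depth <- "intra"
  }
  structure(
    list(name = name, n_layers = n, layer_intensities = layer_intensities,
         layer_thickness = layer_thickness, thickness_jitter = thickness_jitter,
         lesion = lesion, speckle_sigma = speckle_sigma, curvature = curvature,
         background = background),
    class = "oct_class_spec"
  )
}

#' Default five-class synthetic OCT specs
#'
#' Ready-made class specifications emulating the morphology of the usual
#' OCT disease classes at a given image size: `normal` (regular layer
#' stack), `dme_like` (thickened inner layers plus an intraretinal fluid
#' pocket), `amd_like` (bright sub-band dome elevating the RPE band),
#' `hole_like` (full-thickness central gap), `csr_like` (large subretinal
#' fluid dome). Geometric sizes scale with the image height.
#'
#' @param shape image dimensions the specs are intended for
#'   (default `c(128, 128)`).
#' @return Named list of [synthetic_class_spec()] objects.
#' @export
oct_default_specs <- function(shape = c(128, 128)) {
  H <- shape[1]
  u <- H / 128  # geometry scale factor
  base_int <- c(0.55, 0.30, 0.65, 0.25, 0.60, 0.35, 0.75)
  base_thk <- pmax(1, c(6, 8, 7, 9, 7, 6, 5) * u)
  list(
    normal = synthetic_class_spec(
      "normal", base_int, base_thk,
      thickness_jitter = 1 * u),
    dme_like = synthetic_class_spec(
      "dme_like", base_int, pmax(1, c(6, 11, 9, 12, 8, 6, 5) * u),
      thickness_jitter = 1.5 * u,
      lesion = list(type = "dome_fluid", size = c(7, 11) * u, delta = -0.30,
                    depth = "intra")),
    amd_like = synthetic_class_spec(
      "amd_like", base_int, base_thk,
      thickness_jitter = 1 * u,
      lesion = list(type = "sub_band_elevation", size = c(9, 14) * u,
                    delta = 0.15)),
    hole_like = synthetic_class_spec(
      "hole_like", base_int, base_thk,
      thickness_jitter = 1 * u,
      lesion = list(type = "gap", size = c(8, 14) * u, delta = 0)),
    csr_like = synthetic_class_spec(
      "csr_like", base_int, base_thk,
      thickness_jitter = 1 * u,
      lesion = list(type = "dome_fluid", size = c(12, 18) * u, delta = -0.35,
                    depth = "sub"))
  )
}

render_layers <- function(spec, shape, top, thicknesses, curve) {
  H <- shape[1]; W <- shape[2]
  bounds <- top + rbind(0, apply(matrix(thicknesses, ncol = W,
                                        nrow = length(thicknesses)), 2, cumsum))
  bounds <- sweep(bounds, 2, curve, "+")  # (n_layers+1) x W
  rows <- matrix(seq_len(H), H, W)
  im <- matrix(spec$background, H, W)
  for (i in seq_len(spec$n_layers)) {
    lo <- matrix(bounds[i, ], H, W, byrow = TRUE)
    hi <- matrix(bounds[i + 1, ], H, W, byrow = TRUE)
    im[rows >= lo & rows < hi] <- spec$layer_intensities[i]
  }
  list(im = im, bounds = bounds)
}

#' Generate one synthetic OCT-like image
#'
#' Deterministic for a given `(spec, shape, seed)` triple: band boundaries
#' are jittered, the stack is warped by a sinusoid, the lesion (if any) is
#' composited, multiplicative lognormal speckle is applied, and the result
#' is clipped to `[0,1]`.
#'
#' @param spec a [synthetic_class_spec()].
#' @param shape image dimensions (height, width), each >= 32.
#' @param seed integer seed.
#' @return An object of class `"oct_image"`: list with `pixels` (matrix in
#'   `[0,1]`), `source_id`, `label`.
#' @export
generate_image <- function(spec, shape = c(128, 128), seed = 1L) {
  shape <- as.integer(shape)
  if (any(shape < 32L)) stop("shape must be at least 32x32")
  H <- shape[1]; W <- shape[2]
  with_seed(seed, {
    thicknesses <- pmax(1, spec$layer_thickness +
                          stats::rnorm(spec$n_layers, 0, spec$thickness_jitter))
    stack_h <- sum(thicknesses)
    if (stack_h > 0.9 * H) thicknesses <- thicknesses * 0.9 * H / stack_h
    top <- (H - sum(thicknesses)) / 2 + stats::rnorm(1, 0, spec$thickness_jitter)
    phase <- stats::runif(1, 0, 2 * pi)
    curve <- spec$curvature * sin(2 * pi * seq_len(W) / W + phase)
    lesion <- spec$lesion
    size <- if (!is.null(lesion)) stats::runif(1, lesion$size[1], lesion$size[2])
    if (!is.null(lesion) && lesion$type == "band_thickening") {
      band <- sample(seq_len(spec$n_layers), 1)
      thicknesses[band] <- thicknesses[band] + size
    }
    rl <- render_layers(spec, shape, top, thicknesses, curve)
    im <- rl$im
    bounds <- rl$bounds
    if (!is.null(lesion) && lesion$type %in% c("dome_fluid", "gap",
                                               "sub_band_elevation")) {
      cx <- stats::runif(1, 0.3 * W, 0.7 * W)
      col_at_cx <- max(1L, min(W, round(cx)))
      stack_top <- bounds[1, col_at_cx]
      stack_bot <- bounds[nrow(bounds), col_at_cx]
      if (2 * size >= min(H, W) || size >= (stack_bot - stack_top))
        stop("lesion larger than the image / layer stack")
      rows <- matrix(seq_len(H), H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      if (lesion$type == "dome_fluid") {
        cy <- if (identical(lesion$depth, "sub"))
          stack_bot - 0.35 * (stack_bot - stack_top)
        else (stack_top + stack_bot) / 2
        mask <- (rows - cy)^2 + (cols - cx)^2 <= size^2
        im[mask] <- im[mask] + lesion$delta
      } else if (lesion$type == "gap") {
        strip <- abs(cols - cx) <= size / 2
        lo <- matrix(bounds[1, ], H, W, byrow = TRUE)
        hi <- matrix(bounds[nrow(bounds) - 1, ], H, W, byrow = TRUE)
        mask <- strip & rows >= lo & rows < hi
        im[mask] <- spec$background + lesion$delta
      } else {  # sub_band_elevation: bright dome pushing up from the bottom band
        bot <- matrix(bounds[nrow(bounds), ], H, W, byrow = TRUE)
        bump <- pmax(0, size * sqrt(pmax(0, 1 - ((seq_len(W) - cx) / size)^2)))
        bump_m <- matrix(bump, H, W, byrow = TRUE)
        mask <- rows >= bot & rows < bot + bump_m
        im[mask] <- spec$layer_intensities[spec$n_layers] + lesion$delta
      }
    }
    if (spec$speckle_sigma > 0) {
      z <- matrix(stats::rnorm(H * W), H, W)
      im <- im * exp(spec$speckle_sigma * z - spec$speckle_sigma^2 / 2)
    }
    im <- pmin(pmax(im, 0), 1)
    structure(list(pixels = im,
                   source_id = sprintf("synthetic:%s:seed%d", spec$name, seed),
                   label = spec$name),
              class = "oct_image")
  })
}

#' Generate a labeled synthetic dataset
#'
#' Renders `n_per_class` images per class spec, each from a distinct
#' counter-mixed derived seed, together with a manifest recording label,
#' per-image seed and a digest of the generating spec.
#'
#' @param specs list of [synthetic_class_spec()] objects with distinct names.
#' @param n_per_class images per class (>= 1).
#' @param shape image dimensions.
#' @param seed master seed; per-image seeds are derived from it.
#' @return A list with `images` (list of `oct_image`), `labels` (character
#'   vector), `manifest` (data frame with `label`, `index`, `seed`,
#'   `spec_digest`).
#' @export
generate_dataset <- function(specs, n_per_class, shape = c(128, 128), seed = 1L) {
  if (n_per_class < 1) stop("'n_per_class' must be >= 1")
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate class names in 'specs'")
  images <- list()
  manifest <- NULL
  for (k in seq_along(specs)) {
    dg <- spec_digest(specs[[k]])
    for (i in seq_len(n_per_class)) {
      s <- derive_seed(seed, k, i)
      images[[length(images) + 1L]] <- generate_image(specs[[k]], shape, s)
      manifest <- rbind(manifest,
                        data.frame(label = nm[k], index = i, seed = s,
                                   spec_digest = dg))
    }
  }
  list(images = images, labels = manifest$label, manifest = manifest)
}

# FNV-1a hash of the deparsed spec, as a provenance digest.
spec_digest <- function(spec) {
  bytes <- utf8ToInt(paste(deparse(unclass(spec)), collapse = ""))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a synthetic dataset to disk
#'
#' Writes PNG files into per-class subdirectories of `dir` plus a
#' `manifest.csv` with columns `path,label,case_id` — exactly the layout
#' [load_dataset()] consumes.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return The manifest CSV path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- NULL
  for (i in seq_along(dataset$images)) {
    im <- dataset$images[[i]]
    cls_dir <- file.path(dir, im$label)
    dir.create(cls_dir, showWarnings = FALSE)
    case <- sprintf("%s_%04d", im$label, dataset$manifest$index[i])
    rel <- file.path(im$label, paste0(case, ".png"))
    png::writePNG(im$pixels, file.path(dir, rel))
    rows <- rbind(rows, data.frame(path = rel, label = im$label, case_id = case))
  }
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, mf, row.names = FALSE)
  invisible(mf)
}
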