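#' Filter bank parameters
#'
#' Collects the parameters defining a Morlet scattering filter bank: the
#' Gaussian envelope width `sigma`, the central frequency vector `xi` of the
#' prototype wavelet (before rotation), the number of dyadic scales `J`, the
#' number of orientations `r`, and the grid `shape` the filters are sampled
#' on.
#'
#' The orientation set is the `r` equidistant angles \eqn{\{k\pi/r : k =
#' 0,\dots,r-1\}} in \eqn{[0,\pi)}; orientations differing by \eqn{\pi} give
#' conjugate filters, so only half the circle is needed. The invariant scale
#' of the transform is \eqn{2^J} pixels, which must not exceed the grid.
#'
#' @param shape integer vector (height, width) of the sampling grid.
#' @param J number of dyadic scales (positive integer).
#' @param r number of orientations (positive integer, default 12).
#' @param sigma Gaussian envelope width in pixels (default 0.85).
#' @param xi central frequency vector in radians/pixel before rotation;
#'   default `c(3*pi/4, 0)`, i.e. modulus \eqn{3\pi/4} along the first axis.
#' @return An object of class `"wst_filter_params"`.
#' @export
filter_params <- function(shape, J, r = 12L, sigma = 0.85, xi = c(3 * pi / 4, 0)) {
  shape <- as.integer(shape)
  J <- as.integer(J)
  r <- as.integer(r)
  if (length(shape) != 2L || any(shape < 2L))
    stop("'shape' must be two grid dimensions, each >= 2")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  if (J < 1L) stop("'J' must be a positive integer")
  if (r < 1L) stop("'r' must be a positive integer")
  if (length(xi) != 2L || any(!is.finite(xi))) stop("'xi' must be a finite 2-vector")
  if (min(shape) < 2^J)
    stop(sprintf(
      "grid %dx%d too small for J = %d (2^J = %d); maximum admissible J is %d",
      shape[1], shape[2], J, 2^J, floor(log2(min(shape)))
    ))
  structure(
    list(shape = shape, J = J, r = r, sigma = sigma, xi = xi,
         angles = (seq_len(r) - 1L) * pi / r),
    class = "wst_filter_params"
  )
}

# Signed sample coordinates in the wrapped (DFT) layout: index 1 is 0,
# then 1, 2, ..., then the negative side. Matches the standard discrete
# frequency layout so spatial kernels built on these coordinates have their
# phase reference at index (1,1).
wrapped_coords <- function(n) {
  k <- 0:(n - 1L)
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k
}

#' Sampled dilated Gaussian low-pass kernel
#'
#' Samples \eqn{\phi_J(x) = 2^{-2J}\phi(2^{-J}x)} with
#' \eqn{\phi(x) = \frac{1}{2\pi\sigma^2} e^{-|x|^2/2\sigma^2}} on the wrapped
#' grid, optionally renormalizing so the discrete sum is exactly 1 (so that
#' convolution with the kernel preserves constants).
#'
#' @param sigma envelope width in pixels.
#' @param scale_J dilation exponent; the kernel has width `sigma * 2^scale_J`.
#' @param shape grid dimensions (height, width).
#' @param normalize renormalize the sampled kernel to unit sum (default TRUE).
#' @return A real `shape[1] x shape[2]` matrix in the wrapped layout.
#' @export
make_gaussian <- function(sigma, scale_J, shape, normalize = TRUE) {
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  shape <- as.integer(shape)
  if (2^scale_J > min(shape))
    stop(sprintf("scale 2^%d exceeds the grid; maximum admissible J is %d",
                 scale_J, floor(log2(min(shape)))))
  x1 <- wrapped_coords(shape[1])
  x2 <- wrapped_coords(shape[2])
  s2 <- (sigma * 2^scale_J)^2
  g <- (2^(-2 * scale_J) / (2 * pi * sigma^2)) *
    exp(-outer(x1^2, x2^2, "+") / (2 * s2))
  if (normalize) g <- g / sum(g)
  g
}

#' Sampled Morlet band-pass filter (frequency domain)
#'
#' Samples the scaled and rotated Morlet wavelet
#' \eqn{\psi_{j,\gamma}(x) = 2^{-2j}\psi(2^{-j} R_\gamma x)} with prototype
#' \eqn{\psi(x) = c_1 (e^{i\xi\cdot x} - c_2)\,\phi(x)}: a plane wave
#' localized by the Gaussian window, minus the constant \eqn{c_2} that makes
#' the filter exactly zero-mean. \eqn{c_2} is computed from the sampled
#' grids (ratio of the windowed plane-wave sum to the window sum), so the
#' discrete zero-frequency response vanishes exactly; \eqn{c_1} is left at 1
#' here and set by the bank-level Littlewood-Paley normalization
#' ([normalize_bank()]).
#'
#' @param sigma envelope width in pixels.
#' @param xi central frequency 2-vector (radians/pixel) before rotation.
#' @param j dyadic scale index, `0 <= j < J`.
#' @param gamma rotation angle in radians, in `[0, pi)`.
#' @param shape grid dimensions.
#' @return A list with `freq` (complex frequency-domain matrix), `c1`, `c2`.
#' @export
make_morlet <- function(sigma, xi = c(3 * pi / 4, 0), j, gamma, shape) {
  if (gamma < 0 || gamma >= pi) stop("'gamma' must lie in [0, pi)")
  if (j < 0) stop("'j' must be a nonnegative scale index")
  shape <- as.integer(shape)
  x1 <- wrapped_coords(shape[1])
  x2 <- wrapped_coords(shape[2])
  X1 <- matrix(x1, shape[1], shape[2])
  X2 <- matrix(x2, shape[1], shape[2], byrow = TRUE)
  # argument of the prototype: v = 2^{-j} R_gamma x
  v1 <- (cos(gamma) * X1 + sin(gamma) * X2) / 2^j
  v2 <- (-sin(gamma) * X1 + cos(gamma) * X2) / 2^j
  env <- exp(-(v1^2 + v2^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  wave <- exp(1i * (xi[1] * v1 + xi[2] * v2))
  c2 <- sum(wave * env) / sum(env)
  psi <- 2^(-2 * j) * (wave - c2) * env
  list(freq = stats::fft(psi), c1 = 1, c2 = c2)
}

#' Build a Morlet scattering filter bank
#'
#' Constructs the Gaussian low-pass \eqn{\phi_J} and all band-pass filters
#' \eqn{\psi_{j,\gamma}} for scales `j = 0..J-1` and the `r` equidistant
#' orientations, then applies the Littlewood-Paley normalization of
#' [normalize_bank()].
#'
#' @param params a [filter_params()] object.
#' @return An object of class `"wst_filter_bank"` with elements `params`,
#'   `lowpass` (real frequency-domain grid of \eqn{\phi_J}), `bandpass`
#'   (list of complex frequency-domain grids ordered by scale then
#'   orientation), `meta` (data frame of `j`, `gamma_index`, `gamma` per
#'   band-pass filter), `c1`, `c2`, `lp_bound`, `lp_inf`.
#' @export
build_filter_bank <- function(params) {
  if (!inherits(params, "wst_filter_params"))
    stop("'params' must be created by filter_params()")
  shape <- params$shape
  g <- make_gaussian(params$sigma, params$J, shape)
  lowpass <- Re(stats::fft(g))
  meta <- expand.grid(gamma_index = seq_len(params$r) - 1L,
                      j = seq_len(params$J) - 1L)[, 2:1]
  meta$gamma <- params$angles[meta$gamma_index + 1L]
  bandpass <- vector("list", nrow(meta))
  c1 <- numeric(nrow(meta))
  c2 <- complex(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- make_morlet(params$sigma, params$xi, meta$j[i], meta$gamma[i], shape)
    bandpass[[i]] <- m$freq
    c1[i] <- m$c1
    c2[i] <- m$c2
  }
  bank <- structure(
    list(params = params, lowpass = lowpass, bandpass = bandpass,
         meta = meta, c1 = c1, c2 = c2, lp_bound = NA_real_,
         lp_inf = NA_real_),
    class = "wst_filter_bank"
  )
  normalize_bank(bank)
}

# Value grids of the Littlewood-Paley sum components; flip gives A(-omega).
freq_flip <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c(1L, n1:2), c(1L, n2:2), drop = FALSE]
}

#' Littlewood-Paley sum of a filter bank
#'
#' Evaluates \eqn{A(\omega) = |\hat\phi_J(\omega)|^2 + \frac12
#' \sum_{j,\gamma} (|\hat\psi_{j,\gamma}(\omega)|^2 +
#' |\hat\psi_{j,\gamma}(-\omega)|^2)} on the frequency grid. After
#' [normalize_bank()] the supremum of `A` is 1, which makes the scattering
#' transform non-expansive and energy accounting meaningful.
#'
#' @param bank a `"wst_filter_bank"`.
#' @return Real matrix of `A` over the frequency grid (wrapped layout).
#' @export
littlewood_paley <- function(bank) {
  A <- bank$lowpass^2
  for (f in bank$bandpass) {
    m2 <- Mod(f)^2
    A <- A + 0.5 * (m2 + freq_flip(m2))
  }
  A
}

#' Normalize a filter bank to Littlewood-Paley supremum 1
#'
#' Scales all band-pass filters by one common constant so that
#' \eqn{\sup_\omega A(\omega) = 1} (see [littlewood_paley()]). The supremum
#' is always attained at zero frequency, where the low-pass response is 1
#' and every band-pass response vanishes; the common constant is the largest
#' one for which no other frequency exceeds 1.
#'
#' @param bank a `"wst_filter_bank"` (already built).
#' @return The bank with rescaled band-pass filters, updated `c1`, and the
#'   achieved `lp_bound` (supremum) and `lp_inf` (infimum) recorded.
#' @export
normalize_bank <- function(bank) {
  if (!inherits(bank, "wst_filter_bank")) stop("not a filter bank")
  A0 <- bank$lowpass^2
  B <- 0
  for (f in bank$bandpass) {
    m2 <- Mod(f)^2
    B <- B + 0.5 * (m2 + freq_flip(m2))
  }
  if (max(B) <= 0) stop("band-pass filters are identically zero")
  mask <- B > max(B) * 1e-12
  cc2 <- min(pmax(1 - A0[mask], 0) / B[mask])
  cc <- sqrt(cc2)
  bank$bandpass <- lapply(bank$bandpass, function(f) f * cc)
  bank$c1 <- bank$c1 * cc
  A <- A0 + cc2 * B
  bank$lp_bound <- max(A)
  bank$lp_inf <- min(A)
  bank
}

#' @export
print.wst_filter_bank <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Morlet scattering filter bank: %dx%d grid, J = %d, r = %d, sigma = %g\n",
    p$shape[1], p$shape[2], p$J, p$r, p$sigma))
  cat(sprintf("  %d band-pass filters; Littlewood-Paley sup = %.9f, inf = %.4f\n",
              length(x$bandpass), x$lp_bound, x$lp_inf))
  invisible(x)
}

#' Serialize / restore a filter bank or fitted classifier
#'
#' `wst_save()` writes a versioned archive (an RDS file holding the
#' frequency-domain grids or model matrices plus a metadata record);
#' `wst_load()` restores it. Round-tripping a fitted classifier reproduces
#' predictions bit-exactly.
#'
#' @param x a `"wst_filter_bank"` or `"affine_pca"` object.
#' @param path file to write / read.
#' @return `wst_load()` returns the restored object.
#' @export
wst_save <- function(x, path) {
  if (!inherits(x, c("wst_filter_bank", "affine_pca")))
    stop("can only archive filter banks or fitted classifiers")
  saveRDS(list(format = "octscatter-archive", version = 1L,
               class = class(x)[1], payload = unclass(x)),
          path)
  invisible(path)
}

#' @rdname wst_save
#' @export
wst_load <- function(path) {
  a <- readRDS(path)
  if (!identical(a$format, "octscatter-archive"))
    stop("not an octscatter archive")
  structure(a$payload, class = a$class)
}
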