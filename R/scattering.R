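ifft2 <- function(z) stats::fft(z, inverse = TRUE) / length(z)

#' Filter-bank grid for an image shape
#'
#' Rounds image dimensions up to the next multiple of \eqn{2^J} (identity
#' when already aligned): the grid on which the filter bank must be built
#' so the reflection-padded image and the filters share a shape.
#'
#' @param shape image dimensions (height, width).
#' @param J number of scales.
#' @return Integer 2-vector.
#' @export
scattering_shape <- function(shape, J) as.integer(2^J * ceiling(shape / 2^J))

# Reflection-pad (edge included) on the bottom/right to reach `shape`.
reflect_pad <- function(m, shape) {
  dh <- shape[1] - nrow(m)
  dw <- shape[2] - ncol(m)
  if (dh < 0 || dw < 0) stop("target shape smaller than input")
  if (dh > 0) {
    if (dh > nrow(m)) stop("padding exceeds image height")
    m <- rbind(m, m[nrow(m):(nrow(m) - dh + 1L), , drop = FALSE])
  }
  if (dw > 0) {
    if (dw > ncol(m)) stop("padding exceeds image width")
    m <- cbind(m, m[, ncol(m):(ncol(m) - dw + 1L), drop = FALSE])
  }
  m
}

#' FFT convolution with a frequency-domain filter
#'
#' Circular convolution computed as a pointwise product in the frequency
#' domain. If the input grid is smaller than the filter grid, it is first
#' reflection-padded to the filter's shape (mitigating boundary wrap for
#' non-periodic images) and the result is cropped back to the input extent.
#'
#' @param x real or complex input grid.
#' @param filter_freq frequency-domain filter grid (wrapped layout), at
#'   least as large as `x` in both dimensions.
#' @return Complex grid of the same shape as `x`.
#' @export
fft_convolve <- function(x, filter_freq) {
  if (nrow(x) > nrow(filter_freq) || ncol(x) > ncol(filter_freq))
    stop("input larger than filter grid; build the bank on the padded shape")
  h <- nrow(x); w <- ncol(x)
  xp <- reflect_pad(x, dim(filter_freq))
  out <- ifft2(stats::fft(xp) * filter_freq)
  out[seq_len(h), seq_len(w), drop = FALSE]
}

as_pixel_matrix <- function(image) {
  px <- if (inherits(image, "oct_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px)) stop("image must be a numeric matrix or oct_image")
  if (any(!is.finite(px))) stop("image contains non-finite pixels")
  px
}

subsample_grid <- function(m, step) {
  m[seq(1L, nrow(m), by = step), seq(1L, ncol(m), by = step), drop = FALSE]
}

# Canonical path table: order 0, then order 1 by (j1, gamma1), then order 2
# by (j1, gamma1, j2, gamma2). Orientation index is 0-based like the scale.
scattering_paths <- function(J, r, include_equal_scales = FALSE) {
  rows <- list(data.frame(order = 0L, j1 = NA_integer_, g1 = NA_integer_,
                          j2 = NA_integer_, g2 = NA_integer_))
  for (j1 in 0:(J - 1L)) for (g1 in 0:(r - 1L))
    rows[[length(rows) + 1L]] <- data.frame(order = 1L, j1 = j1, g1 = g1,
                                            j2 = NA_integer_, g2 = NA_integer_)
  lo <- if (include_equal_scales) 0L else 1L
  for (j1 in 0:(J - 1L)) for (g1 in 0:(r - 1L)) {
    j2s <- if (j1 + lo <= J - 1L) (j1 + lo):(J - 1L) else integer(0)
    for (j2 in j2s) for (g2 in 0:(r - 1L))
      rows[[length(rows) + 1L]] <- data.frame(order = 2L, j1 = j1, g1 = g1,
                                              j2 = j2, g2 = g2)
  }
  do.call(rbind, rows)
}

path_id <- function(p) {
  ifelse(p$order == 0L, "o0",
         ifelse(p$order == 1L, sprintf("o1.j%d.g%d", p$j1, p$g1),
                sprintf("o2.j%d.g%d.j%d.g%d", p$j1, p$g1, p$j2, p$g2)))
}

#' Number of scattering features
#'
#' The flattened two-layer scattering vector of an `H x W` image with `J`
#' scales and `r` orientations has
#' \deqn{N_J = \left(1 + rJ + r^2 \frac{J(J-1)}{2}\right) 2^{-2J} N, \quad N = HW,}
#' i.e. one low-pass path, `rJ` first-order paths and `r^2 J(J-1)/2`
#' second-order paths (strictly increasing scales), each subsampled on the
#' \eqn{2^J} grid.
#'
#' @param shape image dimensions (height, width).
#' @param J number of scales.
#' @param r number of orientations.
#' @param include_equal_scales also count second-order paths with equal
#'   scales (`j2 == j1`); default FALSE.
#' @return Integer feature count.
#' @export
feature_count <- function(shape, J, r, include_equal_scales = FALSE) {
  sub <- prod(ceiling(shape / 2^J))
  n2 <- if (include_equal_scales) r^2 * J * (J + 1) / 2 else r^2 * J * (J - 1) / 2
  as.integer((1 + r * J + n2) * sub)
}

# Internal cascade. Returns subsampled coefficient grids and, on request,
# the full-resolution low-passed outputs and the order-3 internal modulus
# energy (used by energy_capture). All intermediate modulus fields are kept
# at full resolution.
scatter_engine <- function(px, bank, include_equal_scales = FALSE,
                           keep_full = FALSE, order3_energy = FALSE) {
  p <- bank$params
  J <- p$J; r <- p$r
  target <- scattering_shape(dim(px), J)
  if (!all(target == p$shape))
    stop(sprintf(
      "bank grid is %dx%d but image pads to %dx%d; build the bank with shape = scattering_shape(dim(image), J)",
      p$shape[1], p$shape[2], target[1], target[2]))
  if (min(dim(px)) < 2^J) stop("image smaller than the invariant scale 2^J")
  xp <- reflect_pad(px, p$shape)
  F0 <- stats::fft(xp)
  step <- 2^J
  keep_r <- seq_len(ceiling(nrow(px) / step))
  keep_c <- seq_len(ceiling(ncol(px) / step))
  lowpass_sub <- function(Fu) {
    full <- Re(ifft2(Fu * bank$lowpass))
    list(full = full,
         sub = subsample_grid(full, step)[keep_r, keep_c, drop = FALSE])
  }
  paths <- scattering_paths(J, r, include_equal_scales)
  coefficients <- vector("list", nrow(paths))
  full_out <- if (keep_full) vector("list", nrow(paths)) else NULL

  s0 <- lowpass_sub(F0)
  coefficients[[1L]] <- s0$sub
  if (keep_full) full_out[[1L]] <- s0$full

  band_index <- function(j, g) j * r + g + 1L  # meta is ordered by (j, gamma)
  # first layer moduli at full resolution; the loop nesting below visits
  # paths in exactly the canonical table order, so a running index suffices
  FU1 <- vector("list", J * r)
  i <- 1L
  for (j1 in 0:(J - 1L)) for (g1 in 0:(r - 1L)) {
    b <- band_index(j1, g1)
    U1 <- Mod(ifft2(F0 * bank$bandpass[[b]]))
    FU1[[b]] <- stats::fft(U1)
    s1 <- lowpass_sub(FU1[[b]])
    i <- i + 1L
    coefficients[[i]] <- s1$sub
    if (keep_full) full_out[[i]] <- s1$full
  }
  e3 <- 0
  lo <- if (include_equal_scales) 0L else 1L
  for (j1 in 0:(J - 1L)) for (g1 in 0:(r - 1L)) {
    j2s <- if (j1 + lo <= J - 1L) (j1 + lo):(J - 1L) else integer(0)
    for (j2 in j2s) for (g2 in 0:(r - 1L)) {
      U2 <- Mod(ifft2(FU1[[band_index(j1, g1)]] * bank$bandpass[[band_index(j2, g2)]]))
      FU2 <- stats::fft(U2)
      s2 <- lowpass_sub(FU2)
      i <- i + 1L
      coefficients[[i]] <- s2$sub
      if (keep_full) full_out[[i]] <- s2$full
      if (order3_energy && j2 + 1L <= J - 1L) {
        for (j3 in (j2 + 1L):(J - 1L)) for (g3 in 0:(r - 1L)) {
          U3 <- Mod(ifft2(FU2 * bank$bandpass[[band_index(j3, g3)]]))
          e3 <- e3 + sum(U3^2)
        }
      }
    }
  }
  list(paths = paths, coefficients = coefficients, full = full_out,
       order3_energy = e3, sub_shape = c(length(keep_r), length(keep_c)))
}

#' Two-layer wavelet scattering transform of an image
#'
#' Computes the order-0, order-1 and order-2 scattering coefficients of a
#' grayscale image with a normalized Morlet filter bank: order 0 is the
#' image low-pass filtered with \eqn{\phi_J}; order 1 is
#' \eqn{|f * \psi_{j_1,\gamma_1}| * \phi_J}; order 2 is
#' \eqn{||f * \psi_{j_1,\gamma_1}| * \psi_{j_2,\gamma_2}| * \phi_J} over
#' strictly increasing scale pairs \eqn{j_2 > j_1}. Every output is
#' subsampled on the \eqn{2^J} grid and the results are flattened in the
#' canonical path order (order 0, order 1 by `(j1, gamma1)`, order 2 by
#' `(j1, gamma1, j2, gamma2)`). Intermediate wavelet-modulus fields are kept
#' at full resolution.
#'
#' The image is reflection-padded to the bank's grid (the next multiple of
#' \eqn{2^J} per dimension) before the circular convolutions, and outputs
#' are cropped back, so non-periodic images do not suffer wrap artifacts.
#'
#' @param image numeric matrix with finite entries (intensities, typically
#'   in `[0,1]`) or an `oct_image`.
#' @param bank a normalized `"wst_filter_bank"` built on
#'   `scattering_shape(dim(image), J)`.
#' @param include_equal_scales also compute second-order paths with
#'   `j2 == j1` (sensitivity checks; default FALSE, matching the standard
#'   feature count).
#' @return An object of class `"wst_features"`: list with `paths` (path
#'   table with flat-vector column ranges), `coefficients` (one subsampled
#'   grid per path), `vector` (flattened features, length `n_features`),
#'   `n_features`, and the transform geometry.
#' @export
scatter <- function(image, bank, include_equal_scales = FALSE) {
  px <- as_pixel_matrix(image)
  eng <- scatter_engine(px, bank, include_equal_scales)
  vec <- unlist(lapply(eng$coefficients, as.vector), use.names = FALSE)
  per <- prod(eng$sub_shape)
  paths <- eng$paths
  paths$id <- path_id(paths)
  paths$col_start <- as.integer((seq_len(nrow(paths)) - 1L) * per + 1L)
  paths$col_end <- as.integer(paths$col_start + per - 1L)
  structure(
    list(paths = paths, coefficients = eng$coefficients, vector = vec,
         n_features = length(vec), sub_shape = eng$sub_shape,
         J = bank$params$J, r = bank$params$r, shape = dim(px)),
    class = "wst_features"
  )
}

#' @export
print.wst_features <- function(x, ...) {
  cat(sprintf(
    "Scattering features: %dx%d image, J = %d, r = %d -> %d paths x %dx%d grid = %d features\n",
    x$shape[1], x$shape[2], x$J, x$r, nrow(x$paths),
    x$sub_shape[1], x$sub_shape[2], x$n_features))
  invisible(x)
}

#' Fraction of signal energy captured by scattering orders 0-2
#'
#' Propagating an image through the scattering cascade splits its energy
#' across paths; with a Littlewood-Paley-normalized bank the first three
#' orders usually retain more than 98% of it, which justifies truncating
#' the network at two layers. This returns
#' \eqn{E_{012} / (E_{012} + E_3)}, where \eqn{E_{012}} is the summed
#' squared L2 norm of all order-0, order-1 and order-2 scattering outputs
#' (before subsampling) and \eqn{E_3} is the summed squared norm of all
#' order-3 internal wavelet-modulus signals over increasing-scale paths.
#'
#' @inheritParams scatter
#' @return A fraction in `[0, 1]`.
#' @export
energy_capture <- function(image, bank) {
  px <- as_pixel_matrix(image)
  if (all(px == 0)) stop("energy fraction undefined for an all-zero image")
  if (!is.finite(bank$lp_bound) || abs(bank$lp_bound - 1) > 1e-6)
    stop("bank must be Littlewood-Paley normalized (lp_bound = 1)")
  eng <- scatter_engine(px, bank, keep_full = TRUE, order3_energy = TRUE)
  e012 <- sum(vapply(eng$full, function(m) sum(m^2), numeric(1)))
  e012 / (e012 + eng$order3_energy)
}

#' Scattering feature matrix for a list of images
#'
#' Applies [scatter()] to each image and stacks the flattened feature
#' vectors as rows. All images must share one shape (use the loader's
#' resize policy otherwise).
#'
#' @param images list of numeric matrices or `oct_image` objects.
#' @param bank a normalized `"wst_filter_bank"`.
#' @param include_equal_scales see [scatter()].
#' @return A list with `features` (`n_images x N_J` matrix) and `paths`
#'   (path index table mapping column ranges to scattering paths).
#' @export
extract_features <- function(images, bank, include_equal_scales = FALSE) {
  if (length(images) == 0L) stop("no images")
  dims <- vapply(images, function(im) dim(as_pixel_matrix(im)), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("images have heterogeneous shapes; load with a resize policy first")
  first <- scatter(images[[1L]], bank, include_equal_scales)
  features <- matrix(0, nrow = length(images), ncol = first$n_features)
  features[1L, ] <- first$vector
  if (length(images) > 1L)
    for (i in 2:length(images))
      features[i, ] <- scatter(images[[i]], bank, include_equal_scales)$vector
  list(features = features,
       paths = first$paths[, c("id", "order", "j1", "g1", "j2", "g2",
                               "col_start", "col_end")])
}

#' Export a feature matrix as CSV
#'
#' Columns are labelled `<path id>.px<k>` in the canonical path order, rows
#' are images.
#'
#' @param fs result of [extract_features()].
#' @param path output CSV file.
#' @param labels optional per-row labels, written as a leading column.
#' @export
write_features_csv <- function(fs, path, labels = NULL) {
  per <- fs$paths$col_end[1] - fs$paths$col_start[1] + 1L
  cols <- unlist(lapply(fs$paths$id, function(id) paste0(id, ".px", seq_len(per))))
  df <- as.data.frame(fs$features)
  names(df) <- cols
  if (!is.null(labels)) df <- cbind(label = labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
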