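test_that("Gaussian low-pass kernel is normalized, even, and matches the closed form", {
  for (case in list(c(0, 32), c(2, 64), c(3, 128))) {
    g <- make_gaussian(0.85, case[1], c(case[2], case[2]))
    expect_equal(sum(g), 1, tolerance = 1e-12)
    # even function: invariant under point reflection about the origin
    flipped <- g[c(1, nrow(g):2), c(1, ncol(g):2)]
    expect_lt(max(abs(g - flipped)), 1e-12)
  }
  raw <- make_gaussian(0.85, 0, c(64, 64), normalize = FALSE)
  expect_equal(max(raw), 1 / (2 * pi * 0.85^2), tolerance = 1e-12)
  expect_equal(which(raw == max(raw)), 1L)  # phase reference at index (1,1)
  expect_error(make_gaussian(0.85, 7, c(64, 64)), "maximum admissible J is 6")
})

test_that("Morlet filters are exactly zero-mean and c2 approaches the continuous constant", {
  sh <- c(64, 64)
  for (j in 0:2) for (gamma in c(0, pi / 3, 11 * pi / 12)) {
    m <- make_morlet(0.85, j = j, gamma = gamma, shape = sh)
    expect_lt(Mod(m$freq[1, 1]), 1e-10)
  }
  # oracle: solve int psi = 0 for c2 by integrating the windowed plane wave
  # on a fine sub-pixel grid; compare with the closed form exp(-s^2|xi|^2/2)
  s <- 0.85; xi <- 3 * pi / 4
  u <- seq(-8, 8, by = 0.01)
  env <- exp(-outer(u^2, u^2, "+") / (2 * s^2))
  c2_num <- sum(exp(1i * xi * u) * rowSums(env)) / sum(env)
  expect_equal(Re(c2_num), exp(-s^2 * xi^2 / 2), tolerance = 1e-6)
  expect_lt(abs(Im(c2_num)), 1e-12)
  # the integer-sampled c2 carries a small aliasing correction but stays close
  m0 <- make_morlet(0.85, j = 0, gamma = 0, shape = c(256, 256))
  expect_equal(Re(m0$c2), exp(-s^2 * xi^2 / 2), tolerance = 0.05)
})

test_that("gamma = 0, j = 0 gives the unrotated, unscaled prototype", {
  sh <- c(32, 32)
  m <- make_morlet(0.85, j = 0, gamma = 0, shape = sh)
  # independent construction straight from the definition
  x1 <- c(0:15, -16:-1)
  X1 <- matrix(x1, 32, 32); X2 <- matrix(x1, 32, 32, byrow = TRUE)
  env <- exp(-(X1^2 + X2^2) / (2 * 0.85^2)) / (2 * pi * 0.85^2)
  wave <- exp(1i * (3 * pi / 4) * X1)
  c2 <- sum(wave * env) / sum(env)
  expect_lt(max(Mod(ifft2_h(m$freq) - (wave - c2) * env)), 1e-12)
})

test_that("bank contains J*r zero-mean filters at the equidistant angles", {
  b <- build_filter_bank(filter_params(c(64, 64), J = 2, r = 12))
  expect_length(b$bandpass, 24L)
  expect_equal(sort(unique(b$meta$gamma)), (0:11) * pi / 12)
  expect_true(all(vapply(b$bandpass, function(f) Mod(f[1, 1]), 0) < 1e-10))
  b1 <- build_filter_bank(filter_params(c(32, 32), J = 1, r = 1))
  expect_length(b1$bandpass, 1L)
  expect_equal(b1$meta$gamma, 0)
  expect_error(filter_params(c(8, 8), J = 4), "maximum admissible J")
})

test_that("Littlewood-Paley normalization reaches sup 1 and is scale invariant", {
  b <- build_filter_bank(filter_params(c(128, 128), J = 3, r = 8))
  A <- littlewood_paley(b)
  expect_equal(max(A), 1, tolerance = 1e-9)
  expect_equal(b$lp_bound, max(A))
  # rescaling the unnormalized bank must not change the normalized result
  b2 <- b
  b2$bandpass <- lapply(b2$bandpass, function(f) f * 3.7)
  b2 <- normalize_bank(b2)
  expect_lt(max(mapply(function(f, g) max(Mod(f - g)), b$bandpass, b2$bandpass)),
            1e-12)
  # frame coverage dip sits between phi_J and the coarsest wavelet;
  # regression value recorded from this construction (sigma = 0.85)
  w <- 2 * pi * c(0:63, -64:-1) / 128
  R2 <- outer(w^2, w^2, "+")
  inf_band <- min(A[R2 < (pi / 2)^2])
  expect_gt(inf_band, 0.25)
  expect_equal(inf_band, 0.27159, tolerance = 1e-3)
})

test_that("rotating the prototype composes: grid rotation by pi/2 matches the rotated filter", {
  sh <- c(32, 32)
  psi0 <- ifft2_h(make_morlet(0.85, j = 1, gamma = 0, shape = sh)$freq)
  psi90 <- ifft2_h(make_morlet(0.85, j = 1, gamma = pi / 2, shape = sh)$freq)
  # psi_{pi/2}(x) = psi_0(R_{pi/2} x): value at coords (x1,x2) taken from
  # coords (x2,-x1); exclude the asymmetric -n/2 coordinate line
  n <- 32L
  idx_of <- function(v) ((v %% n) + 1L)
  coords <- c(0:(n / 2 - 1), -(n / 2):-1)
  keep <- which(coords != -n / 2)
  err <- 0
  for (a in keep) for (b in keep) {
    x1 <- coords[a]; x2 <- coords[b]
    err <- max(err, Mod(psi90[a, b] - psi0[idx_of(x2), idx_of(-x1)]))
  }
  expect_lt(err, 1e-10)
  # composing two pi/2 rotations (rotation by pi) re-enters [0, pi) as the
  # conjugate prototype: psi_0(-x) = conj(psi_0(x))
  flip <- psi0[c(1, n:2), c(1, n:2)]
  expect_lt(max(Mod(flip - Conj(psi0))), 1e-10)
})

test_that("wavelet passbands halve in radius as the scale increments", {
  b <- build_filter_bank(filter_params(c(128, 128), J = 3, r = 4))
  w <- 2 * pi * c(0:63, -64:-1) / 128
  Rm <- sqrt(outer(w^2, w^2, "+"))
  peak_radius <- function(j) {
    f <- b$bandpass[[j * b$params$r + 1L]]  # gamma = 0 filter at scale j
    Rm[which.max(Mod(f))]
  }
  for (j in 0:1)
    expect_lt(abs(peak_radius(j + 1) - peak_radius(j) / 2),
              0.1 * peak_radius(j) / 2)
})

test_that("bank archives round-trip through wst_save/wst_load", {
  b <- build_filter_bank(filter_params(c(32, 32), J = 2, r = 4))
  f <- tempfile(fileext = ".bin")
  wst_save(b, f)
  b2 <- wst_load(f)
  expect_identical(class(b2), "wst_filter_bank")
  expect_identical(b$bandpass, b2$bandpass)
  expect_identical(b$lp_bound, b2$lp_bound)
})
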