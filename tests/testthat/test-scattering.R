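test_that("fft_convolve has the delta identity, preserves constants, and matches direct summation", {
  set.seed(3)
  x <- matrix(runif(64), 8, 8)
  expect_lt(max(Mod(fft_convolve(x, matrix(1 + 0i, 8, 8)) - x)), 1e-10)
  g <- make_gaussian(0.85, 1, c(8, 8))
  const <- matrix(0.37, 8, 8)
  expect_lt(max(abs(Re(fft_convolve(const, fft(g))) - 0.37)), 1e-10)
  k <- matrix(rnorm(64) + 1i * rnorm(64), 8, 8)
  got <- fft_convolve(x, fft(k))
  want <- conv2_circular_direct(x, k)
  expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-8)
  expect_error(fft_convolve(matrix(0, 9, 9), fft(k)), "larger than")
})

test_that("a constant image has constant order-0 and vanishing order-1/2 coefficients", {
  bank <- build_filter_bank(filter_params(c(64, 64), J = 2, r = 4))
  s <- scatter(matrix(0.6, 64, 64), bank)
  o0 <- s$vector[s$paths$col_start[1]:s$paths$col_end[1]]
  expect_lt(max(abs(o0 - 0.6)), 1e-8)
  expect_lt(max(abs(s$vector[-(s$paths$col_start[1]:s$paths$col_end[1])])), 1e-8)
})

test_that("feature counts follow (1 + rJ + r^2 J(J-1)/2) 2^-2J N", {
  cases <- list(c(64, 64, 2, 12, 43264), c(32, 32, 2, 4, 1600),
                c(128, 128, 3, 8, 55552), c(64, 64, 1, 6, 7168),
                c(128, 64, 3, 12, 60032))
  for (cs in cases) {
    sh <- cs[1:2]; J <- cs[3]; r <- cs[4]
    n2 <- r^2 * J * (J - 1) / 2
    expect_identical(feature_count(sh, J, r),
                     as.integer((1 + r * J + n2) * prod(sh) / 4^J))
    expect_identical(feature_count(sh, J, r), as.integer(cs[5]))
  }
  im <- textured_image(c(64, 64), 5)
  s <- scatter(im, build_filter_bank(filter_params(c(64, 64), J = 2, r = 12)))
  expect_identical(s$n_features, 43264L)
  # equal-scale flag adds the j2 == j1 paths
  s2 <- scatter(im, build_filter_bank(filter_params(c(64, 64), J = 2, r = 12)),
                include_equal_scales = TRUE)
  expect_identical(s2$n_features, feature_count(c(64, 64), 2, 12,
                                                include_equal_scales = TRUE))
  expect_gt(s2$n_features, s$n_features)
})

test_that("paths are enumerated canonically with increasing second-layer scales", {
  bank <- build_filter_bank(filter_params(c(64, 64), J = 3, r = 2))
  s <- scatter(textured_image(c(64, 64), 1), bank)
  p <- s$paths
  expect_identical(p$order[1], 0L)
  o1 <- p[p$order == 1L, ]
  expect_identical(o1$j1, rep(0:2, each = 2))
  expect_identical(o1$g1, rep(0:1, 3))
  o2 <- p[p$order == 2L, ]
  expect_true(all(o2$j2 > o2$j1))
  expect_false(is.unsorted(o2$j1))
  expect_identical(nrow(o2), as.integer(2^2 * 3 * 2 / 2))
  # column ranges tile the vector exactly
  expect_identical(p$col_start[-1], p$col_end[-nrow(p)] + 1L)
  expect_identical(p$col_end[nrow(p)], s$n_features)
})

test_that("order-1/2 coefficients are nonnegative and the transform is non-expansive", {
  bank <- build_filter_bank(filter_params(c(32, 32), J = 2, r = 4))
  for (seed in 1:5) {
    set.seed(seed)
    f <- matrix(runif(1024), 32, 32)
    g <- matrix(runif(1024), 32, 32)
    sf <- scatter(f, bank)
    sg <- scatter(g, bank)
    expect_gt(min(sf$vector[-(1:64)]), -1e-12)
    expect_lte(sqrt(sum((sf$vector - sg$vector)^2)),
               sqrt(sum((f - g)^2)) * 1.05)
  }
})

test_that("translation sensitivity shrinks as the invariant scale grows", {
  im <- textured_image(c(64, 64), 9)
  rel <- vapply(2:4, function(J) {
    b <- build_filter_bank(filter_params(c(64, 64), J = J, r = 4))
    rel_l2(scatter(circ_shift(im, 2), b)$vector, scatter(im, b)$vector)
  }, numeric(1))
  expect_true(all(diff(rel) < 0))
  expect_lt(rel[3], 0.10)
})

test_that("full scattering agrees with the brute-force spatial oracle", {
  bank <- build_filter_bank(filter_params(c(16, 16), J = 2, r = 2))
  im <- textured_image(c(32, 32), 13)[1:16, 1:16]
  got <- scatter(im, bank)$vector
  want <- scatter_bruteforce(im, bank)
  expect_lt(rel_l2(got, want), 1e-8)
})

test_that("energy capture is a valid fraction and saturates for a smooth blob", {
  bank <- build_filter_bank(filter_params(c(64, 64), J = 3, r = 4))
  x <- outer((1:64 - 32.5)^2, (1:64 - 32.5)^2, "+")
  blob <- exp(-x / (2 * 20^2))
  fr <- energy_capture(blob, bank)
  expect_gt(fr, 0.999)
  expect_lte(fr, 1)
  fr2 <- energy_capture(textured_image(c(64, 64), 21), bank)
  expect_gte(fr2, 0)
  expect_lte(fr2, 1)
  expect_error(energy_capture(matrix(0, 64, 64), bank), "all-zero")
  unnorm <- build_filter_bank(filter_params(c(64, 64), J = 3, r = 4))
  unnorm$lp_bound <- 2
  expect_error(energy_capture(blob, unnorm), "normalized")
})

test_that("extract_features is consistent, deterministic, and order-equivariant", {
  bank <- build_filter_bank(filter_params(c(32, 32), J = 2, r = 2))
  ims <- lapply(1:3, function(s) textured_image(c(32, 32), s))
  fs <- extract_features(c(ims, ims[1]), bank)
  expect_identical(fs$features[1, ], scatter(ims[[1]], bank)$vector)
  expect_identical(fs$features[1, ], fs$features[4, ])
  perm <- extract_features(ims[c(3, 1, 2)], bank)
  expect_identical(perm$features, fs$features[c(3, 1, 2), ])
  expect_error(extract_features(list(ims[[1]], matrix(0, 16, 16)), bank),
               "resize")
  csv <- tempfile(fileext = ".csv")
  write_features_csv(fs, csv, labels = c("a", "b", "c", "a"))
  back <- read.csv(csv)
  expect_identical(dim(back), c(4L, fs$features |> ncol() + 1L))
  expect_equal(unname(as.matrix(back[, -1])), fs$features, tolerance = 1e-12)
})

test_that("images that are not multiples of 2^J are reflection-padded, not rejected", {
  J <- 3
  im <- textured_image(c(64, 64), 2)[1:60, 1:57]
  bank <- build_filter_bank(filter_params(scattering_shape(dim(im), J), J = J, r = 2))
  s <- scatter(im, bank)
  expect_identical(s$sub_shape, c(8L, 8L))  # ceil(60/8), ceil(57/8)
  wrong <- build_filter_bank(filter_params(c(128, 128), J = J, r = 2))
  expect_error(scatter(im, wrong), "scattering_shape")
  expect_error(scatter(matrix(1, 4, 4), build_filter_bank(
    filter_params(c(8, 8), J = 3, r = 2))), "padding exceeds|smaller")
})
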