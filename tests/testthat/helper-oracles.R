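# Independent oracles and small fixtures used across the suite.

# O(N^2) direct-space circular convolution: out[m,n] = sum_{p,q} x[p,q] *
# k[(m-p) mod H, (n-q) mod W]. Deliberately avoids the FFT route it checks.
conv2_circular_direct <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0 + 0i, H, W)
  for (p in seq_len(H)) {
    ridx <- ((seq_len(H) - p) %% H) + 1L
    for (q in seq_len(W)) {
      cidx <- ((seq_len(W) - q) %% W) + 1L
      out <- out + x[p, q] * k[ridx, cidx]
    }
  }
  out
}

ifft2_h <- function(z) stats::fft(z, inverse = TRUE) / length(z)

# Spatial kernels of a bank (inverse transform of the frequency grids).
bank_spatial_kernels <- function(bank) {
  list(phi = Re(ifft2_h(bank$lowpass + 0i)),
       psi = lapply(bank$bandpass, ifft2_h))
}

# Brute-force scattering oracle: the same mathematical cascade, but every
# convolution done by direct spatial summation. Image dims must equal the
# bank grid (no padding path).
scatter_bruteforce <- function(px, bank) {
  ker <- bank_spatial_kernels(bank)
  J <- bank$params$J; r <- bank$params$r
  step <- 2^J
  sub <- function(m) m[seq(1, nrow(m), by = step), seq(1, ncol(m), by = step)]
  lp <- function(u) Re(conv2_circular_direct(u, ker$phi))
  out <- list(as.vector(sub(lp(px))))
  U1 <- list()
  for (j1 in 0:(J - 1)) for (g1 in 0:(r - 1)) {
    b <- j1 * r + g1 + 1L
    U1[[b]] <- Mod(conv2_circular_direct(px, ker$psi[[b]]))
    out[[length(out) + 1L]] <- as.vector(sub(lp(U1[[b]])))
  }
  for (j1 in 0:(J - 1)) for (g1 in 0:(r - 1)) {
    if (j1 + 1 > J - 1) next
    for (j2 in (j1 + 1):(J - 1)) for (g2 in 0:(r - 1)) {
      U2 <- Mod(conv2_circular_direct(U1[[j1 * r + g1 + 1L]],
                                      ker$psi[[j2 * r + g2 + 1L]]))
      out[[length(out) + 1L]] <- as.vector(sub(lp(U2)))
    }
  }
  unlist(out)
}

# Least-squares projection residual: distance from v to mean + span(B),
# solved explicitly through the normal equations (qr), independent of the
# orthonormal-basis shortcut in the package.
residual_lstsq_oracle <- function(v, mean, B) {
  w <- v - mean
  if (ncol(B) == 0) return(sqrt(sum(w^2)))
  coef <- qr.coef(qr(B), w)
  sqrt(sum((w - B %*% coef)^2))
}

# Principal angles (degrees) between the column spans of two orthonormal
# bases.
principal_angles <- function(B1, B2) {
  s <- svd(t(B1) %*% B2)$d
  acos(pmin(pmax(s, -1), 1)) * 180 / pi
}

circ_shift <- function(m, s1, s2 = s1) {
  H <- nrow(m); W <- ncol(m)
  m[((seq_len(H) - 1 - s1) %% H) + 1, ((seq_len(W) - 1 - s2) %% W) + 1]
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# K well-separated affine classes in p dimensions: mean + rank-d_true
# latent structure + isotropic noise; inter-mean distances ~ sep * noise.
make_affine_data <- function(seed, K = 3, p = 200, d_true = 5, n_k = 60,
                             noise = 1, sep = 10) {
  set.seed(seed)
  x <- NULL; y <- NULL
  means <- qr.Q(qr(matrix(rnorm(p * K), p, K))) * sep * noise * sqrt(2)
  for (k in seq_len(K)) {
    B <- qr.Q(qr(matrix(rnorm(p * d_true), p, d_true)))
    z <- matrix(rnorm(n_k * d_true, sd = 2 * noise), n_k, d_true)
    x <- rbind(x, matrix(means[, k], n_k, p, byrow = TRUE) + z %*% t(B) +
                 matrix(rnorm(n_k * p, sd = noise), n_k, p))
    y <- c(y, rep(paste0("c", k), n_k))
  }
  list(x = x, y = y)
}

# Seeded textured fixture: a synthetic B-scan with speckle.
textured_image <- function(shape = c(128, 128), seed = 42) {
  generate_image(oct_default_specs(shape)$normal, shape, seed)$pixels
}
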