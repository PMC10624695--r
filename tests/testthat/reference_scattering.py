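"""Reference two-layer Morlet scattering transform, written independently in
NumPy from the mathematical definitions (Gaussian low-pass phi_J, zero-mean
Morlet band-pass filters on r equidistant angles in [0, pi), common-constant
Littlewood-Paley normalization to supremum 1, modulus cascade, 2^J
subsampling, canonical path order). Used by the test suite as an
independent oracle for full feature vectors.

Usage: python reference_scattering.py image.csv J r sigma out.csv
The image side lengths must be multiples of 2^J.
"""
import sys

import numpy as np


def grid(shape):
    x1 = np.fft.fftfreq(shape[0]) * shape[0]
    x2 = np.fft.fftfreq(shape[1]) * shape[1]
    return np.meshgrid(x1, x2, indexing="ij")


def gaussian(sigma, J, shape):
    X1, X2 = grid(shape)
    s2 = (sigma * 2.0**J) ** 2
    g = 2.0 ** (-2 * J) / (2 * np.pi * sigma**2) * np.exp(-(X1**2 + X2**2) / (2 * s2))
    return g / g.sum()


def morlet(sigma, xi, j, gamma, shape):
    X1, X2 = grid(shape)
    v1 = (np.cos(gamma) * X1 + np.sin(gamma) * X2) / 2.0**j
    v2 = (-np.sin(gamma) * X1 + np.cos(gamma) * X2) / 2.0**j
    env = np.exp(-(v1**2 + v2**2) / (2 * sigma**2)) / (2 * np.pi * sigma**2)
    wave = np.exp(1j * (xi * v1))
    c2 = (wave * env).sum() / env.sum()
    return np.fft.fft2(2.0 ** (-2 * j) * (wave - c2) * env)


def build_bank(shape, J, r, sigma, xi=3 * np.pi / 4):
    phi_hat = np.real(np.fft.fft2(gaussian(sigma, J, shape)))
    psis = [
        morlet(sigma, xi, j, k * np.pi / r, shape)
        for j in range(J)
        for k in range(r)
    ]
    A0 = phi_hat**2
    B = np.zeros(shape)
    for p in psis:
        m2 = np.abs(p) ** 2
        B += 0.5 * (m2 + m2[np.ix_(*(np.r_[0, s - 1 : 0 : -1] for s in shape))])
    mask = B > B.max() * 1e-12
    cc = np.sqrt(np.min(np.maximum(1 - A0[mask], 0) / B[mask]))
    return phi_hat, [p * cc for p in psis]


def scatter(image, J, r, sigma):
    shape = image.shape
    phi_hat, psis = build_bank(shape, J, r, sigma)
    step = 2**J
    low = lambda F: np.real(np.fft.ifft2(F * phi_hat))[::step, ::step]
    F0 = np.fft.fft2(image)
    out = [low(F0).ravel(order="F")]
    U1 = {}
    for j1 in range(J):
        for g1 in range(r):
            U1[j1, g1] = np.abs(np.fft.ifft2(F0 * psis[j1 * r + g1]))
            out.append(low(np.fft.fft2(U1[j1, g1])).ravel(order="F"))
    for j1 in range(J):
        for g1 in range(r):
            F1 = np.fft.fft2(U1[j1, g1])
            for j2 in range(j1 + 1, J):
                for g2 in range(r):
                    U2 = np.abs(np.fft.ifft2(F1 * psis[j2 * r + g2]))
                    out.append(low(np.fft.fft2(U2)).ravel(order="F"))
    return np.concatenate(out)


def main():
    image_csv, J, r, sigma, out_csv = sys.argv[1:6]
    image = np.loadtxt(image_csv, delimiter=",")
    vec = scatter(image, int(J), int(r), float(sigma))
    np.savetxt(out_csv, vec)


if __name__ == "__main__":
    main()
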