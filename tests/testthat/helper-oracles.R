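# Independent oracles used across the suite. These deliberately avoid the
# package's own closed-form expressions: slabs are Fourier-transformed by
# numerical quadrature and smearing is checked against adaptive integration.

# Thin-sheet intensity of a uniform slab of thickness L by brute-force
# numerical Fourier transform of the thickness profile (unit density on
# [-L/2, L/2]), normalised to C at q -> 0: I(q) = C * (F(q)/L)^2 / q^2.
oracle_slab_intensity <- function(q, L, C = 1, n_z = 4001) {
  z <- seq(-L / 2, L / 2, length.out = n_z)
  vapply(q, function(qi) {
    Fq <- pracma::trapz(z, cos(qi * z))
    C * (Fq / L)^2 / qi^2
  }, numeric(1))
}

# Gaussian q-smearing of a model function by adaptive quadrature.
oracle_smear <- function(f, q, spread) {
  vapply(q, function(qi) {
    s <- qi * spread / 2.355
    norm <- stats::integrate(function(u) stats::dnorm(u, qi, s),
                             lower = 1e-9, upper = qi + 10 * s)$value
    stats::integrate(function(u) f(u) * stats::dnorm(u, qi, s),
                     lower = 1e-9, upper = qi + 10 * s)$value / norm
  }, numeric(1))
}

# Ordinary least squares Kratky-Porod fit done "by hand" on arbitrary
# (q, I) values: returns d_g. Independent of kratky_porod_fit internals.
oracle_kp_dg <- function(q, I, window = c(0.31, 1.14)) {
  sel <- q >= window[1] & q <= window[2]
  x <- q[sel]^2
  y <- log(I[sel] * q[sel]^2)
  slope <- stats::cov(x, y) / stats::var(x)
  sqrt(12) * sqrt(-slope)
}

# Dense brute-force scan for the mode and FWHM of a sampled curve.
oracle_mode_fwhm <- function(x, y) {
  i <- which.max(y)
  half <- y[i] / 2
  iL <- i; while (iL > 1 && y[iL - 1] > half) iL <- iL - 1
  iR <- i; while (iR < length(y) && y[iR + 1] > half) iR <- iR + 1
  xL <- stats::approx(y[c(iL - 1, iL)], x[c(iL - 1, iL)], xout = half)$y
  xR <- stats::approx(y[c(iR, iR + 1)], x[c(iR, iR + 1)], xout = half)$y
  list(mode = x[i], fwhm = xR - xL)
}
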