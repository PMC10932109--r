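# internal numerics shared across modules

# sin(x)/x with the x -> 0 limit
sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)

# trapezoidal integral on an arbitrary grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Gauss-Legendre nodes/weights on [a, b]
gauss_legendre <- function(n, a, b) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

# spherical Bessel j_l(x) for a vector x and a single order l >= 0
sph_bessel_j <- function(l, x) {
  out <- numeric(length(x))
  small <- x < 1e-6
  out[small] <- if (l == 0) 1 else 0
  xs <- x[!small]
  if (length(xs)) out[!small] <- besselJ(xs, l + 0.5) * sqrt(pi / (2 * xs))
  out
}

# real/imag spherical-harmonic factors N_lm * P_lm(cos(theta)) for m = 0..l,
# rows = points, cols = m; phase factor exp(-i m phi) applied by caller
assoc_legendre_norm <- function(l, cos_theta) {
  # pracma::legendre returns (l+1) x n matrix of P_l^m, m = 0..l
  P <- pracma::legendre(l, cos_theta)
  if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
  m <- 0:l
  norm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
  t(P * norm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
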