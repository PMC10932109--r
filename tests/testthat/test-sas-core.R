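test_that("scattering_curve enforces its invariants", {
  expect_s3_class(scattering_curve(1:3 / 10, c(1, 2, 3)), "scattering_curve")
  expect_error(scattering_curve(c(0.1, 0.1, 0.2), 1:3), "increasing")
  expect_error(scattering_curve(c(-0.1, 0.1), 1:2), "> 0")
  expect_error(scattering_curve(c(0.1, 0.2), c(1, NA)), "finite")
  expect_error(scattering_curve(c(0.1, 0.2), 1:2, c(1, -1)), "sigma")
  expect_error(scattering_curve(c(0.1, 0.2), 1:3), "equal length")
})

test_that("curve text round trip preserves data", {
  crv <- guinier_curve(sigma_rel = 0.02)
  f <- withr::local_tempfile(fileext = ".dat")
  write_curve(crv, f)
  back <- read_curve(f)
  expect_equal(back$q, crv$q, tolerance = 1e-7)
  expect_equal(back$intensity, crv$intensity, tolerance = 1e-7)
  expect_equal(back$sigma, crv$sigma, tolerance = 1e-6)
})

test_that("rebinning: identity, constant preservation, and pooling", {
  crv <- guinier_curve(sigma_rel = 0.05)
  same <- rebin_curve(crv, length(crv$q))
  expect_equal(same$q, crv$q)
  expect_equal(same$intensity, crv$intensity)

  const <- scattering_curve(seq(0.01, 0.1, 0.001), rep(7, 91))
  for (nb in c(3, 10, 91))
    expect_true(all(abs(rebin_curve(const, nb)$intensity - 7) < 1e-12))

  # two points, sigmas 1 and 2: hand-computed inverse-variance pooling
  two <- scattering_curve(c(0.1, 0.2), c(10, 20), c(1, 2))
  rb <- rebin_curve(two, 1)
  w <- c(1, 1 / 4)
  expect_equal(rb$intensity, sum(w * c(10, 20)) / sum(w))
  expect_equal(rb$sigma, sqrt(1 / sum(w)))

  expect_error(rebin_curve(two, 3), "exceeds")
})

test_that("nested rebinning equals direct rebinning", {
  set.seed(1)
  q <- seq(0.01, 0.2, length.out = 40)
  i <- exp(-q^2 * 300) * (1 + 0.05 * rnorm(40))
  crv <- scattering_curve(q, i, 0.02 * abs(i) + 1e-4)
  twostep <- rebin_curve(rebin_curve(crv, 20), 10)
  onestep <- rebin_curve(crv, 10)
  expect_equal(twostep$q, onestep$q, tolerance = 1e-12)
  expect_equal(twostep$intensity, onestep$intensity, tolerance = 1e-12)
  expect_equal(twostep$sigma, onestep$sigma, tolerance = 1e-12)
})

test_that("smearing preserves constants, is identity at zero spread, and
           never raises the maximum", {
  q <- seq(0.02, 0.25, length.out = 150)
  const <- scattering_curve(q, rep(3.5, 150))
  sm <- smear_resolution(const, resolution_spec(6, 0.10))
  expect_equal(sm$intensity, const$intensity, tolerance = 1e-12)

  crv <- guinier_curve()
  expect_identical(smear_resolution(crv, resolution_spec(6, 0)), crv)

  peaked <- scattering_curve(q, intensity_sphere(q, 40))
  smp <- smear_resolution(peaked, resolution_spec(6, 0.10))
  expect_lte(max(smp$intensity), max(peaked$intensity) + 1e-12)
})

test_that("smearing width matches a brute-force dense-grid convolution", {
  # narrow Gaussian feature; oracle convolves on a 10x denser grid
  q0 <- 0.1; w <- 0.002
  q <- seq(0.06, 0.14, length.out = 400)
  crv <- scattering_curve(q, exp(-(q - q0)^2 / (2 * w^2)))
  res <- resolution_spec(6, 0.10)
  out <- smear_resolution(crv, res)

  qd <- seq(0.05, 0.15, length.out = 4000)
  id <- exp(-(qd - q0)^2 / (2 * w^2))
  sig_k <- q0 * 0.10 / 2.355
  kern <- stats::dnorm(qd, q0, sig_k)
  kern[abs(qd - q0) > 3 * sig_k] <- 0
  oracle_peak <- sum(kern * id) / sum(kern)

  gauss_width <- function(qv, iv) {
    # moment-based width of a peaked profile
    iv <- pmax(iv, 0)
    mu <- sum(qv * iv) / sum(iv)
    sqrt(sum((qv - mu)^2 * iv) / sum(iv))
  }
  expected_w <- sqrt(w^2 + sig_k^2)
  expect_equal(gauss_width(out$q, out$intensity), expected_w,
               tolerance = 0.03)
  # peak height agrees with the dense-grid oracle at q0
  expect_equal(out$intensity[which.min(abs(q - q0))], oracle_peak,
               tolerance = 0.02)
})

test_that("Kratky classification separates folded from unfolded", {
  q <- seq(0.01, 0.25, length.out = 120)
  compact <- scattering_curve(q, intensity_elliptical_cylinder(q, tbl1_low()))
  expect_identical(compute_kratky(compact)$classification, "folded")

  chain <- scattering_curve(q, q^-2)          # ideal-chain high-q behaviour
  expect_identical(compute_kratky(chain)$classification, "unfolded")

  short <- scattering_curve(q[1:5], q[1:5]^-2)
  expect_warning(kp <- compute_kratky(short), "fewer than 10")
  expect_identical(kp$classification, "indeterminate")
})

test_that("Kratky peak location matches dense-grid maximization and the
           classification is scale invariant", {
  # oracle: maximize Q^2 * P_sphere(Q) on a dense grid
  qd <- seq(0.001, 0.25, length.out = 20000)
  q0 <- qd[which.max(qd^2 * intensity_sphere(qd, 30))]

  q <- seq(0.005, 0.25, length.out = 300)
  kp <- compute_kratky(scattering_curve(q, intensity_sphere(q, 30)))
  expect_lt(abs(kp$q[which.max(kp$q2i)] - q0), 2 * diff(q)[1])
  expect_true(all(abs(kp$q2i - kp$q^2 * intensity_sphere(q, 30)) < 1e-14))

  for (c_scale in c(1e-3, 1, 500)) {
    sc <- compute_kratky(scattering_curve(q, c_scale * intensity_sphere(q, 30)))
    expect_identical(sc$classification, kp$classification)
  }
})
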