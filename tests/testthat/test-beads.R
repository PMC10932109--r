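test_that("bead_model enforces spacing and symmetry invariants", {
  expect_error(bead_model(rbind(c(0, 0, 0), c(1, 0, 0)), 3), "closer")
  expect_error(bead_model(rbind(c(10, 0, 0), c(0, 10, 0)), 3,
                          symmetry = "P2"), "P2")
  ok <- bead_model(rbind(c(10, 0, 0), c(-10, 0, 0)), 3, symmetry = "P2")
  expect_s3_class(ok, "bead_model")
})

test_that("single-bead intensity is the bead form factor and both backends
           coincide", {
  m <- bead_model(matrix(c(0, 0, 0), 1), 4)
  q <- seq(0.01, 0.3, length.out = 40)
  i_multi <- bead_intensity(m, q, "multipole")
  i_debye <- bead_intensity(m, q, "debye")
  expect_equal(i_multi, i_debye, tolerance = 1e-10)
  x <- q * 4
  ff2 <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  expect_equal(i_debye, ff2, tolerance = 1e-10)
})

test_that("two beads at distance d follow the closed-form Debye pair sum", {
  d <- 25
  m <- bead_model(rbind(c(0, 0, -d / 2), c(0, 0, d / 2)), 3)
  q <- seq(0.01, 0.3, length.out = 40)
  x <- q * 3
  ff2 <- (3 * (sin(x) - x * cos(x)) / x^3)^2
  expected <- ff2 * 2 * (1 + sin(q * d) / (q * d))
  expect_equal(bead_intensity(m, q, "debye"), expected, tolerance = 1e-10)
  expect_equal(bead_intensity(m, q, "multipole"), expected,
               tolerance = 1e-5)
})

test_that("multipole and Debye backends agree within 1% on a random
           bead cloud", {
  lat <- bead_lattice(50, 2.5)
  set.seed(21)
  m <- bead_model(lat$sites[sample(nrow(lat$sites), 50), ], 2.5)
  q <- seq(0.01, 0.25, length.out = 30)
  i_m <- bead_intensity(m, q, "multipole")
  i_d <- bead_intensity(m, q, "debye")
  expect_lt(max(abs(i_m - i_d) / i_d), 0.01)
})

test_that("an undersized lmax is raised with a warning", {
  lat <- bead_lattice(50, 2.5)
  set.seed(22)
  m <- bead_model(lat$sites[sample(nrow(lat$sites), 30), ], 2.5)
  q <- seq(0.01, 0.25, length.out = 20)
  expect_warning(i1 <- bead_intensity(m, q, "multipole", lmax = 2),
                 "raised")
  i2 <- bead_intensity(m, q, "multipole")
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("NSD: zero for identical models, symmetric, closed form for
           single-bead pairs", {
  m <- blob_model()
  expect_equal(nsd(m, m), 0, tolerance = 1e-12)

  set.seed(31)
  lat <- bead_lattice(40, 2)
  a <- bead_model(lat$sites[sample(nrow(lat$sites), 20), ], 2)
  b <- bead_model(lat$sites[sample(nrow(lat$sites), 25), ], 2)
  expect_equal(nsd(a, b), nsd(b, a), tolerance = 1e-12)

  d <- 7; rb <- 2
  one <- bead_model(matrix(c(0, 0, 0), 1), rb)
  two <- bead_model(matrix(c(d, 0, 0), 1), rb)
  expect_equal(nsd(one, two), d / (2 * rb), tolerance = 1e-12)
})

test_that("alignment: self-alignment of a rotated copy, idempotence,
           single-model centering", {
  m <- blob_model()
  mc <- m
  mc$coordinates <- m$coordinates %*% t(rotate_x(0.4) %*% rotate_z(0.7))
  mc$coordinates <- sweep(mc$coordinates, 2, c(5, -3, 2), `+`)
  al <- align_models(list(m, mc))
  expect_lt(nsd(al[[1]], al[[2]]), 0.05)

  al2 <- align_models(al)
  expect_lt(max(abs(al[[1]]$coordinates - al2[[1]]$coordinates)), 1e-6)
  expect_lt(max(abs(al[[2]]$coordinates - al2[[2]]$coordinates)), 1e-6)

  single <- align_models(list(mc))
  expect_equal(colMeans(single[[1]]$coordinates), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("averaging: identical models pass through, an outlier run is
           removed at the 0.5 cut", {
  m <- blob_model()
  avg <- average_models(list(m, m, m), occupancy_cut = 0.5)
  expect_equal(nrow(avg$coordinates), nrow(m$coordinates))
  expect_true(all(avg$occupancy == 1))

  outlier <- m
  outlier$coordinates <- sweep(m$coordinates, 2, c(200, 0, 0), `+`)
  avg2 <- average_models(list(m, m, m, outlier), occupancy_cut = 0.5)
  expect_true(all(avg2$coordinates[, 1] < 100))
  expect_equal(nrow(avg2$coordinates), nrow(m$coordinates))

  expect_identical(average_models(list(m)), m)
  expect_error(average_models(list(m, outlier), occupancy_cut = 0.9),
               "occupancy_cut")
})

test_that("bead models survive a PDB write/read round trip", {
  m <- blob_model(dmax = 40, bead_radius = 4, semi = c(16, 10, 8))
  m$occupancy <- rep(c(1, 0.5), length.out = nrow(m$coordinates))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_bead_model(m, f)
  back <- read_bead_model(f)
  expect_equal(back$coordinates, m$coordinates, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$occupancy, m$occupancy, tolerance = 1e-2)
  expect_equal(back$bead_radius, 4)
})

# one full sphere-target reconstruction shared by the blocks below
sphere_target <- scattering_curve(seq(0.01, 0.25, length.out = 60),
                                  intensity_sphere(
                                    seq(0.01, 0.25, length.out = 60), 30))
sphere_recon <- reconstruct_shape(sphere_target, 60, "P1",
                                  anneal_config(seed = 7))

test_that("sphere-target reconstruction recovers the shape (NSD < 1) and
           improves on the initial configuration", {
  lat <- bead_lattice(60, sphere_recon$bead_radius)
  truth <- bead_model(lat$sites[rowSums(lat$sites^2) <= 900, ],
                      sphere_recon$bead_radius)
  al <- align_models(list(truth, sphere_recon))
  expect_lt(nsd(al[[1]], al[[2]]), 1.0)
  expect_lt(attr(sphere_recon, "chi2"), attr(sphere_recon, "chi2_initial"))
  trace <- attr(sphere_recon, "score_trace")
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("reconstruction is reproducible from its seed", {
  cfg <- anneal_config(seed = 13, max_stages = 6)
  crv <- scattering_curve(seq(0.01, 0.25, length.out = 40),
                          intensity_sphere(
                            seq(0.01, 0.25, length.out = 40), 20))
  m1 <- reconstruct_shape(crv, 40, "P1", cfg)
  m2 <- reconstruct_shape(crv, 40, "P1", cfg)
  expect_identical(m1$coordinates, m2$coordinates)
})

test_that("P2 reconstructions satisfy the two-fold symmetry exactly", {
  crv <- scattering_curve(seq(0.01, 0.25, length.out = 40),
                          intensity_sphere(
                            seq(0.01, 0.25, length.out = 40), 20))
  m <- reconstruct_shape(crv, 40, "P2", anneal_config(seed = 17,
                                                      max_stages = 8))
  xyz <- m$coordinates
  rot <- cbind(-xyz[, 1], -xyz[, 2], xyz[, 3])
  dev <- max(vapply(seq_len(nrow(rot)), function(i)
    min(sqrt((xyz[, 1] - rot[i, 1])^2 + (xyz[, 2] - rot[i, 2])^2 +
               (xyz[, 3] - rot[i, 3])^2)), numeric(1)))
  expect_lt(dev, 1e-9)
  expect_identical(m$symmetry, "P2")
})

test_that("reconstruction rejects curves that are too short", {
  crv <- scattering_curve(seq(0.01, 0.1, length.out = 10), rep(1, 10))
  expect_error(reconstruct_shape(crv, 40, "P1"), "at least 20")
})

test_that("the reconstructed cylinder has the generating length within
           15%", {
  q <- seq(0.008, 0.13, length.out = 50)
  crv <- scattering_curve(q, intensity_elliptical_cylinder(q, tbl1_low()))
  m <- reconstruct_shape(crv, 95, "P1", anneal_config(seed = 11))
  expect_lt(abs(bead_extent(m) - 73) / 73, 0.15)
})
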