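vacuum <- contrast_params(solvent_sld = 0)

test_that("PDB reading: coordinates, residue ranges, unknown elements", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2      10.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  st <- read_structure(f)
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$xyz[2, 1], 10)

  chain <- withr::local_tempfile(fileext = ".pdb")
  write_ca_chain_pdb(chain, 310)
  sel <- read_structure(chain, residue_range = c(30, 300))
  expect_equal(range(sel$atoms$resno), c(30, 300))
  expect_equal(nrow(sel$atoms), 271)
  expect_error(read_structure(chain, residue_range = c(500, 600)),
               "no atoms")

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  XX  UNK A   1       0.000   0.000   0.000  1.00  0.00          XX",
    "END"), bad)
  expect_error(read_structure(bad), "scattering length")
})

test_that("implicit hydrogens follow the united-atom counts", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CB  ALA A   1       2.100   1.200   0.000  1.00  0.00           C",
    "ATOM      4  NZ  LYS A   2       5.000   0.000   0.000  1.00  0.00           N",
    "END"), f)
  st <- read_structure(f)
  expect_equal(st$atoms$h_total, c(1, 1, 3, 3))
  expect_equal(st$atoms$h_labile, c(1, 0, 0, 3))
})

test_that("one- and two-atom Debye curves follow the closed forms", {
  s1 <- atomic_structure("C", matrix(c(1, 2, 3), 1))
  q <- seq(0.01, 0.3, length.out = 40)
  crv <- debye_intensity(s1, q, vacuum)
  b <- 6.646
  expect_equal(crv$intensity, rep(b^2, 40), tolerance = 1e-10)

  d <- 10
  s2 <- atomic_structure(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  crv2 <- debye_intensity(s2, q, vacuum)
  expect_equal(crv2$intensity, 2 * b^2 * (1 + sin(q * d) / (q * d)),
               tolerance = 1e-10)
})

test_that("I(0) equals the squared sum of contrast weights", {
  set.seed(41)
  st <- atomic_structure(sample(c("C", "N", "O", "S"), 60, replace = TRUE),
                         matrix(rnorm(180, sd = 10), ncol = 3))
  ct <- contrast_params(d2o_fraction = 0.4)
  i0 <- debye_intensity(st, 1e-6, ct)$intensity
  g <- st$atoms$b_heavy - ct$solvent_sld * st$atoms$vol
  expect_equal(i0, sum(g)^2, tolerance = 1e-6)
})

test_that("Guinier Rg of the Debye curve equals the contrast-weighted
           second moment within 1%", {
  set.seed(42)
  xyz <- matrix(rnorm(240, sd = 12), ncol = 3)
  st <- atomic_structure(rep("C", 80), xyz)
  crv <- debye_intensity(st, seq(0.002, 0.05, length.out = 80), vacuum)
  cen <- colMeans(xyz)
  rg_coord <- sqrt(mean(rowSums(sweep(xyz, 2, cen)^2)))
  fit <- fit_guinier(crv, qrg_window = c(0.1, 1.0))
  expect_equal(fit$rg, rg_coord, tolerance = 0.01)
})

test_that("Debye intensity is invariant under rigid motion of the whole
           structure", {
  set.seed(43)
  xyz <- matrix(rnorm(150, sd = 8), ncol = 3)
  st <- atomic_structure(rep("N", 50), xyz)
  q <- seq(0.01, 0.3, length.out = 30)
  i1 <- debye_intensity(st, q, vacuum)$intensity
  st2 <- st
  st2$xyz <- sweep(xyz %*% t(rotate_x(1.1) %*% rotate_z(0.3)), 2,
                   c(100, -50, 20), `+`)
  i2 <- debye_intensity(st2, q, vacuum)$intensity
  expect_equal(i1, i2, tolerance = 1e-12)
})

test_that("with zero solvent and equal b the Debye curve matches the bead
           Debye backend", {
  set.seed(44)
  lat <- bead_lattice(40, 2)
  xyz <- lat$sites[sample(nrow(lat$sites), 40), ]
  st <- atomic_structure(rep("C", 40), xyz)
  q <- seq(0.01, 0.25, length.out = 30)
  i_at <- debye_intensity(st, q, vacuum)$intensity
  m <- bead_model(xyz, 0.01)     # point-like beads: form factor ~ 1
  i_bd <- bead_intensity(m, q, "debye")
  b <- 6.646
  expect_equal(i_at / b^2, i_bd, tolerance = 1e-6)
})

test_that("rigid-body fit: fixed point, planted translation, argmin
           property, clash detection", {
  set.seed(45)
  blk1 <- atomic_structure(rep("C", 30), matrix(rnorm(90, sd = 8), ncol = 3))
  blk2 <- atomic_structure(rep("N", 25),
                           sweep(matrix(rnorm(75, sd = 6), ncol = 3), 2,
                                 c(30, 0, 0), `+`))
  q <- seq(0.01, 0.3, length.out = 40)
  grid <- as.matrix(expand.grid(seq(-10, 10, 5), seq(-10, 10, 5),
                                seq(-10, 10, 5)))

  target0 <- debye_intensity(
    atomic_structure(c(rep("C", 30), rep("N", 25)),
                     rbind(blk1$xyz, blk2$xyz)), q, vacuum)
  fit0 <- rigid_body_fit(blk1, blk2, target0, translations = grid,
                         contrast = vacuum)
  expect_equal(unname(fit0$translation), c(0, 0, 0))
  expect_lt(fit0$chi2, 1e-15)

  tr <- c(5, -5, 0)
  moved <- sweep(blk2$xyz, 2, tr, `+`)
  target <- debye_intensity(
    atomic_structure(c(rep("C", 30), rep("N", 25)),
                     rbind(blk1$xyz, moved)), q, vacuum)
  fit <- rigid_body_fit(blk1, blk2, target, translations = grid,
                        contrast = vacuum)
  expect_equal(unname(fit$translation), tr)
  expect_lte(fit$chi2, fit$chi2_initial)

  overlapping <- atomic_structure(rep("N", 25), blk1$xyz[1:25, ])
  expect_error(rigid_body_fit(blk1, overlapping, target0,
                              translations = matrix(0, 1, 3),
                              contrast = vacuum), "clash")
})
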