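# shared fixtures and independent oracles, all generated in code

# exact Guinier-law curve
guinier_curve <- function(rg = 30, i0 = 2.5, q = seq(0.005, 0.2, 0.002),
                          sigma_rel = NULL) {
  i <- i0 * exp(-q^2 * rg^2 / 3)
  scattering_curve(q, i, if (!is.null(sigma_rel)) sigma_rel * i)
}

# Table-1 elliptical-cylinder geometries
tbl1_low <- function(scale = 1)
  elliptical_cylinder_params(14.64, 2.07, 73, scale = scale)
tbl1_high <- function(scale = 1)
  elliptical_cylinder_params(13.49, 2.06, 100, scale = scale)

# smeared noise-free model curve on the wide Q grid
smeared_model_curve <- function(params, q = seq(0.005, 0.25,
                                                length.out = 200)) {
  smear_resolution(scattering_curve(
    q, intensity_elliptical_cylinder(q, params)))
}

# uniform random points in a sphere (rejection sampling)
mc_sphere_points <- function(n, radius, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  while (nrow(pts) < n) {
    cand <- matrix(stats::runif(3 * 2 * n, -radius, radius), ncol = 3)
    cand <- cand[rowSums(cand^2) <= radius^2, , drop = FALSE]
    pts <- rbind(pts, cand)
  }
  pts[seq_len(n), ]
}

# uniform random points in an elliptical cylinder (axis along z)
mc_ecyl_points <- function(n, a, nu, L, seed = 1) {
  set.seed(seed)
  pts <- matrix(numeric(0), 0, 3)
  b <- nu * a
  while (nrow(pts) < n) {
    x <- stats::runif(2 * n, -a, a)
    y <- stats::runif(2 * n, -b, b)
    keep <- (x / a)^2 + (y / b)^2 <= 1
    z <- stats::runif(sum(keep), -L / 2, L / 2)
    pts <- rbind(pts, cbind(x[keep], y[keep], z))
  }
  pts[seq_len(n), ]
}

# brute-force orientation-averaged intensity of a point cloud (Debye sum),
# normalized to 1 at Q = 0. Averaging over distinct pairs only gives an
# unbiased estimate of the continuum double integral (the self-pair term
# is a 1/n granularity bias that dominates where I(Q) is small).
mc_debye <- function(pts, q) {
  d <- as.vector(stats::dist(pts))
  vapply(q, function(qq) {
    x <- qq * d
    mean(ifelse(x < 1e-9, 1, sin(x) / x))
  }, numeric(1))
}

# analytic normalized P(r) of a homogeneous sphere of radius R
sphere_pr_analytic <- function(r, R) {
  x <- r / (2 * R)
  p <- 3 * r^2 / (2 * R)^3 * (2 - 3 * x + x^3) * 2   # shape only
  p[r < 0 | r > 2 * R] <- 0
  p
}

# a small blob-shaped bead model on the lattice for alignment tests
blob_model <- function(dmax = 60, bead_radius = 3,
                       semi = c(28, 14, 9)) {
  lat <- bead_lattice(dmax, bead_radius)
  s <- lat$sites
  idx <- which((s[, 1] / semi[1])^2 + (s[, 2] / semi[2])^2 +
                 (s[, 3] / semi[3])^2 <= 1)
  bead_model(s[idx, , drop = FALSE], bead_radius)
}

rotate_z <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, byrow = TRUE)
rotate_x <- function(theta)
  matrix(c(1, 0, 0,
           0, cos(theta), -sin(theta),
           0, sin(theta), cos(theta)), 3, byrow = TRUE)

# minimal PDB text for synthetic chains: one CA carbon per residue
write_ca_chain_pdb <- function(path, n_res, chain = "A",
                               spacing = 3.8) {
  lines <- vapply(seq_len(n_res), function(i)
    sprintf("ATOM  %5d  CA  GLY %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, chain, i, i * spacing, 0, 0), character(1))
  writeLines(c(lines, "END"), path)
  path
}
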