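#' Dummy-atom (bead) model
#'
#' A low-resolution shape represented by equal spheres ("beads") on a
#' lattice. `occupancy` is 1 for raw reconstructions and fractional after
#' multi-run averaging. Under `P2` symmetry the bead set maps onto itself
#' under a 180 degree rotation about the z axis.
#'
#' @param coordinates Numeric matrix (n x 3) of bead centers (Angstrom).
#' @param bead_radius Bead radius (Angstrom, > 0).
#' @param symmetry `"P1"` or `"P2"`.
#' @param occupancy Optional per-bead weights in `[0, 1]` (default 1).
#' @param tol Geometric tolerance for the invariant checks (Angstrom).
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(coordinates, bead_radius, symmetry = c("P1", "P2"),
                       occupancy = NULL, tol = 1e-6) {
  coordinates <- as.matrix(coordinates)
  if (ncol(coordinates) != 3 || nrow(coordinates) < 1)
    stop("'coordinates' must be a non-empty n x 3 matrix", call. = FALSE)
  stopifnot_scalar(bead_radius, "bead_radius")
  symmetry <- match.arg(symmetry)
  n <- nrow(coordinates)
  occupancy <- occupancy %||% rep(1, n)
  if (length(occupancy) != n || any(occupancy < 0 | occupancy > 1))
    stop("'occupancy' must be per-bead values in [0, 1]", call. = FALSE)
  if (n > 1 && n <= 4000) {
    dmin <- min(stats::dist(coordinates))
    if (dmin < 2 * bead_radius - max(tol, 1e-3 * bead_radius))
      stop("bead centers closer than the lattice spacing", call. = FALSE)
  }
  if (symmetry == "P2" && !.is_p2(coordinates, max(tol, 1e-3)))
    stop("coordinates do not satisfy P2 symmetry about the z axis",
         call. = FALSE)
  structure(list(coordinates = coordinates, bead_radius = bead_radius,
                 symmetry = symmetry, occupancy = occupancy),
            class = "bead_model")
}

# does the point set map onto itself under 180 deg rotation about z?
.is_p2 <- function(xyz, tol) {
  rot <- cbind(-xyz[, 1], -xyz[, 2], xyz[, 3])
  for (i in seq_len(nrow(rot))) {
    d2 <- (xyz[, 1] - rot[i, 1])^2 + (xyz[, 2] - rot[i, 2])^2 +
      (xyz[, 3] - rot[i, 3])^2
    if (min(d2) > tol^2) return(FALSE)
  }
  TRUE
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Bead model: %d beads, radius %.2f A, symmetry %s\n",
              nrow(x$coordinates), x$bead_radius, x$symmetry))
  invisible(x)
}

#' Hexagonal bead lattice inside a search sphere
#'
#' Close-packed hexagonal layers (in-plane spacing 2 * `bead_radius`,
#' layer spacing sqrt(3) * `bead_radius`, alternate layers offset by half
#' a row) clipped to the sphere of diameter `dmax`. The stacking is chosen
#' to be exactly closed under a 180 degree rotation about z, so P2
#' symmetry can be enforced by pairing each site with its rotational mate.
#'
#' @param dmax Search-sphere diameter (Angstrom).
#' @param bead_radius Bead radius (Angstrom); lattice spacing is twice
#'   this.
#' @return A list: `sites` (n x 3 matrix), `spacing`, `mate` (index of the
#'   180-degree mate of each site; equals the own index on the axis) and
#'   `neighbors` (list of indices of touching sites).
#' @export
bead_lattice <- function(dmax, bead_radius) {
  stopifnot_scalar(dmax, "dmax")
  stopifnot_scalar(bead_radius, "bead_radius")
  a <- 2 * bead_radius
  rmax <- dmax / 2
  h <- a * sqrt(3) / 2
  ks <- seq(-floor(rmax / h), floor(rmax / h))
  pts <- list()
  for (k in ks) {
    z <- k * h
    xoff <- if (k %% 2 == 0) 0 else a / 2
    rk <- sqrt(max(rmax^2 - z^2, 0))
    js <- seq(-floor((rk + a) / h), floor((rk + a) / h))
    for (j in js) {
      y <- j * h
      row_off <- if (j %% 2 == 0) 0 else a / 2
      x0 <- xoff + row_off
      is <- seq(-floor((rk + a) / a) - 1, floor((rk + a) / a) + 1)
      x <- x0 + is * a
      keep <- x^2 + y^2 + z^2 <= rmax^2
      if (any(keep))
        pts[[length(pts) + 1]] <- cbind(x[keep], y, z)
    }
  }
  sites <- do.call(rbind, pts)
  # mate under (x, y) -> (-x, -y): locate by rounded-coordinate key
  key <- function(m) paste(round(m[, 1] / a * 4), round(m[, 2] / a * 4),
                           round(m[, 3] / a * 4))
  idx <- stats::setNames(seq_len(nrow(sites)), key(sites))
  mk <- key(cbind(-sites[, 1], -sites[, 2], sites[, 3]))
  mate <- unname(idx[mk])
  # drop sites whose mate fell outside the clip sphere
  keep <- !is.na(mate)
  sites <- sites[keep, , drop = FALSE]
  idx <- stats::setNames(seq_len(nrow(sites)), key(sites))
  mate <- unname(idx[key(cbind(-sites[, 1], -sites[, 2], sites[, 3]))])
  nb_cut2 <- (1.05 * a)^2
  nb <- lapply(seq_len(nrow(sites)), function(i) {
    d2 <- (sites[, 1] - sites[i, 1])^2 + (sites[, 2] - sites[i, 2])^2 +
      (sites[, 3] - sites[i, 3])^2
    which(d2 > 1e-9 & d2 <= nb_cut2)
  })
  list(sites = sites, spacing = a, mate = mate, neighbors = nb)
}

# sphere amplitude of a single bead
.bead_ff_amp <- function(q, radius) {
  x <- q * radius
  ifelse(x < 1e-6, 1 - x^2 / 10, 3 * (sin(x) - x * cos(x)) / x^3)
}

# default multipole truncation from the sampling theorem: the number of
# resolvable angular channels scales with Qmax * rmax
.auto_lmax <- function(qmax, rmax) max(5L, min(24L, ceiling(qmax * rmax) + 3L))

# multipole machinery: per-order spherical Bessel factors and
# weight * Y*_lm factors for a point set
.multipole_parts <- function(xyz, weights, q, lmax) {
  r <- sqrt(rowSums(xyz^2))
  ct <- ifelse(r < 1e-12, 1, xyz[, 3] / r)
  phi <- atan2(xyz[, 2], xyz[, 1])
  JL <- vector("list", lmax + 1)
  B <- vector("list", lmax + 1)
  for (l in 0:lmax) {
    JL[[l + 1]] <- outer(q, r, function(qq, rr) sph_bessel_j(l, qq * rr))
    P <- assoc_legendre_norm(l, ct)                      # n x (l+1)
    E <- exp(-1i * outer(phi, 0:l))                      # n x (l+1)
    B[[l + 1]] <- (weights * P) * E
  }
  list(JL = JL, B = B)
}

# I(q) (without bead form factor) from multipole coefficient list C
.multipole_intensity <- function(C) {
  out <- 0
  for (l in seq_along(C)) {
    M <- C[[l]]
    a2 <- Mod(M)^2
    out <- out + a2[, 1] + if (ncol(M) > 1) 2 * rowSums(a2[, -1, drop = FALSE]) else 0
  }
  4 * pi * out
}

#' Scattering intensity of a bead model
#'
#' Two backends compute the orientation-averaged intensity of a weighted
#' bead set, both modulated by the single-bead sphere form factor. The
#' `debye` backend is the exact double sum
#' I(Q) = F_bead(Q)^2 sum_ij w_i w_j sin(Q r_ij)/(Q r_ij). The
#' `multipole` backend expands the scattering amplitude in spherical
#' harmonics with spherical Bessel radial factors and sums
#' I(Q) = 2 pi^2 sum_lm |A_lm(Q)|^2, truncated at `lmax`; the default
#' truncation grows with Qmax * rmax following the sampling-theorem rule
#' and is raised automatically (with a warning) if too small for the
#' requested Q range.
#'
#' @param model A [bead_model()].
#' @param q Scattering-vector grid (1/Angstrom).
#' @param backend `"multipole"` or `"debye"`.
#' @param lmax Multipole truncation order (default: automatic).
#' @return Vector of intensities.
#' @export
bead_intensity <- function(model, q, backend = c("multipole", "debye"),
                           lmax = NULL) {
  stopifnot(inherits(model, "bead_model"))
  backend <- match.arg(backend)
  xyz <- model$coordinates
  w <- model$occupancy
  ff2 <- .bead_ff_amp(q, model$bead_radius)^2
  if (backend == "debye") {
    d <- as.matrix(stats::dist(xyz))
    out <- vapply(q, function(qq) sum(outer(w, w) * sinc(qq * d)),
                  numeric(1))
    return(ff2 * out)
  }
  rmax <- max(sqrt(rowSums(xyz^2)), 1e-9)
  auto <- .auto_lmax(max(q), rmax)
  if (!is.null(lmax) && lmax < auto) {
    warning(sprintf(
      "lmax = %d too small for Qmax * rmax = %.1f; raised to %d",
      lmax, max(q) * rmax, auto))
    lmax <- auto
  }
  lmax <- lmax %||% auto
  parts <- .multipole_parts(xyz, w, q, lmax)
  C <- lapply(0:lmax, function(l) parts$JL[[l + 1]] %*% parts$B[[l + 1]])
  ff2 * .multipole_intensity(C)
}

#' Annealing configuration for shape reconstruction
#'
#' Defaults: the starting temperature is set automatically to the
#' standard deviation of score changes over 100 random bead toggles;
#' cooling multiplies the temperature by 0.9 per stage; each stage
#' attempts 20 moves per initial bead; annealing stops after 3
#' consecutive stages improving the best score by less than 1%. The bead
#' radius defaults to dmax/20, giving lattices of a few hundred sites.
#'
#' @param n_beads_initial Number of beads in the random starting
#'   configuration (default: half the lattice sites).
#' @param t_start Initial temperature (default: automatic).
#' @param cooling Multiplicative cooling factor per stage, in (0, 1).
#' @param moves_per_stage Moves attempted per stage (default: 20 x
#'   initial bead count).
#' @param compactness_weight Penalty coefficient on the fraction of beads
#'   with fewer than 3 occupied neighbors.
#' @param seed RNG seed; the reconstruction is reproducible given it.
#' @param lmax Multipole truncation order (default: automatic).
#' @param bead_radius Lattice bead radius (default: dmax/20).
#' @param max_stages Hard cap on temperature stages.
#' @return An object of class `anneal_config`.
#' @export
anneal_config <- function(n_beads_initial = NULL, t_start = NULL,
                          cooling = 0.9, moves_per_stage = NULL,
                          compactness_weight = 0.3, seed = 1,
                          lmax = NULL, bead_radius = NULL,
                          max_stages = 60) {
  if (cooling <= 0 || cooling >= 1)
    stop("'cooling' must be in (0, 1)", call. = FALSE)
  structure(list(n_beads_initial = n_beads_initial, t_start = t_start,
                 cooling = cooling, moves_per_stage = moves_per_stage,
                 compactness_weight = compactness_weight, seed = seed,
                 lmax = lmax, bead_radius = bead_radius,
                 max_stages = max_stages),
            class = "anneal_config")
}

#' Ab initio shape reconstruction by simulated annealing
#'
#' Dummy-atom reconstruction in the spirit of bead-model Monte Carlo
#' methods: beads live on a hexagonal lattice inside a sphere of diameter
#' `dmax`; moves toggle a random bead (and, under `P2`, its 180-degree
#' mate about z simultaneously, so the symmetry holds exactly by
#' construction); Metropolis acceptance on the score
#' chi^2(curve, scaled model intensity) + compactness_weight x looseness,
#' where looseness is the fraction of beads with fewer than 3 occupied
#' neighbors. The model intensity is maintained incrementally through the
#' multipole expansion. The best configuration seen is returned, pruned
#' to its largest connected component.
#'
#' @param curve A [scattering_curve()] (at least 20 points).
#' @param dmax Search-sphere diameter (Angstrom).
#' @param symmetry `"P1"` or `"P2"`.
#' @param config An [anneal_config()].
#' @return A [bead_model()] with attributes `chi2` (final), `chi2_initial`
#'   and `score_trace` (per-stage best scores).
#' @export
reconstruct_shape <- function(curve, dmax, symmetry = c("P1", "P2"),
                              config = anneal_config()) {
  stopifnot(inherits(curve, "scattering_curve"))
  stopifnot_scalar(dmax, "dmax")
  symmetry <- match.arg(symmetry)
  if (length(curve$q) < 20)
    stop("curve must have at least 20 points for reconstruction",
         call. = FALSE)
  # moderate grid keeps the incremental updates cheap
  work <- if (length(curve$q) > 60) rebin_curve(curve, 60) else curve
  q <- work$q
  I_d <- work$intensity
  sig <- work$sigma %||% pmax(0.01 * abs(I_d), 1e-5 * max(abs(I_d)))
  wts <- 1 / sig^2
  nq <- length(q)

  r_bead <- config$bead_radius %||% (dmax / 20)
  lat <- bead_lattice(dmax, r_bead)
  ns <- nrow(lat$sites)
  lmax <- config$lmax %||% .auto_lmax(max(q), dmax / 2)
  parts <- .multipole_parts(lat$sites, rep(1, ns), q, lmax)
  ff2 <- .bead_ff_amp(q, r_bead)^2

  # orbits: singletons (on-axis) or {site, mate} pairs under P2
  if (symmetry == "P2") {
    orb <- lapply(seq_len(ns), function(i) sort(unique(c(i, lat$mate[i]))))
    orb <- unique(orb)
  } else {
    orb <- as.list(seq_len(ns))
  }
  norb <- length(orb)

  set.seed(config$seed)
  occ <- rep(FALSE, ns)
  n_init <- config$n_beads_initial %||% round(ns / 2)
  sel <- sample.int(norb, max(1, min(norb, round(n_init / mean(lengths(orb))))))
  for (o in sel) occ[orb[[o]]] <- TRUE

  # multipole coefficients of the occupied set
  C <- lapply(0:lmax, function(l)
    parts$JL[[l + 1]][, occ, drop = FALSE] %*%
      parts$B[[l + 1]][occ, , drop = FALSE])
  nb_count <- vapply(seq_len(ns), function(i) sum(occ[lat$neighbors[[i]]]),
                     numeric(1))

  model_int <- function() ff2 * .multipole_intensity(C)
  chi2_of <- function(Im) {
    cc <- sum(wts * I_d * Im) / sum(wts * Im^2)
    sum(wts * (I_d - cc * Im)^2) / nq
  }
  looseness <- function() {
    nb_occ <- sum(occ)
    if (nb_occ == 0) return(1)
    sum(nb_count[occ] < 3) / nb_occ
  }
  score_now <- function() chi2_of(model_int()) + config$compactness_weight * looseness()

  apply_orbit <- function(o) {
    for (j in orb[[o]]) {
      s <- if (occ[j]) -1 else 1
      for (l in 0:lmax) {
        C[[l + 1]] <<- C[[l + 1]] +
          s * outer(parts$JL[[l + 1]][, j], parts$B[[l + 1]][j, ])
      }
      occ[j] <<- !occ[j]
      nbs <- lat$neighbors[[j]]
      nb_count[nbs] <<- nb_count[nbs] + s
    }
  }

  chi2_initial <- chi2_of(model_int())
  score <- score_now()

  t_start <- config$t_start
  if (is.null(t_start)) {
    deltas <- numeric(100)
    for (k in 1:100) {
      o <- sample.int(norb, 1)
      s0 <- score
      apply_orbit(o)
      deltas[k] <- score_now() - s0
      apply_orbit(o)                       # revert
    }
    t_start <- max(stats::sd(deltas), 1e-12)
  }

  n_beads0 <- sum(occ)
  mps <- config$moves_per_stage %||% (20 * n_beads0)
  temp <- t_start
  best_score <- score
  best_occ <- occ
  trace <- numeric(0)
  stall <- 0
  min_beads <- max(10, round(n_beads0 / 20))

  for (stage in seq_len(config$max_stages)) {
    accepted <- 0
    stage_best_in <- best_score
    for (mv in seq_len(mps)) {
      o <- sample.int(norb, 1)
      turning_off <- occ[orb[[o]][1]]
      if (turning_off && sum(occ) - length(orb[[o]]) < min_beads) next
      s0 <- score
      apply_orbit(o)
      s1 <- score_now()
      if (s1 <= s0 || stats::runif(1) < exp(-(s1 - s0) / temp)) {
        score <- s1
        accepted <- accepted + 1
        if (s1 < best_score) {
          best_score <- s1
          best_occ <- occ
        }
      } else {
        apply_orbit(o)                     # reject
      }
    }
    trace <- c(trace, best_score)
    if (accepted == 0)
      stop("annealing stalled: no move accepted in a temperature stage",
           call. = FALSE)
    improve <- (stage_best_in - best_score) / max(stage_best_in, 1e-12)
    stall <- if (improve < 0.01) stall + 1 else 0
    if (stall >= 3) break
    temp <- temp * config$cooling
  }

  # largest connected component of the best configuration
  occ_idx <- which(best_occ)
  comp <- .largest_component(occ_idx, lat$neighbors)
  xyz <- lat$sites[comp, , drop = FALSE]
  final <- bead_model(xyz, r_bead, symmetry = "P1")
  final$symmetry <- symmetry              # symmetry tag of the run
  if (symmetry == "P2" && !.is_p2(xyz, 1e-3))
    final$symmetry <- "P1"                # pruning broke an axis pair
  Imod <- bead_intensity(final, q, backend = "multipole", lmax = lmax)
  attr(final, "chi2") <- chi2_of(Imod)
  attr(final, "chi2_initial") <- chi2_initial
  attr(final, "score_trace") <- trace
  final
}

.largest_component <- function(occ_idx, neighbors) {
  if (!length(occ_idx)) return(occ_idx)
  inset <- logical(max(unlist(neighbors), occ_idx))
  inset[occ_idx] <- TRUE
  seen <- logical(length(inset))
  best <- integer(0)
  for (s in occ_idx) {
    if (seen[s]) next
    stack <- s
    comp <- integer(0)
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- neighbors[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      seen[nb] <- TRUE
      stack <- c(stack, nb)
    }
    if (length(comp) > length(best)) best <- comp
  }
  sort(best)
}

#' Align bead models for averaging
#'
#' Each model is centered on its centroid and rotated to its principal
#' axes (eigenvectors of the coordinate covariance, ordered by decreasing
#' extent, right-handed). Models after the first are additionally flipped
#' through the four proper axis-sign combinations and the flip minimizing
#' the normalized spatial discrepancy to the first model is kept.
#' Alignment is idempotent up to tolerance.
#'
#' @param models List of [bead_model()] objects (length >= 1).
#' @return List of aligned [bead_model()] objects.
#' @export
align_models <- function(models) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  lapply(models, function(m) stopifnot(inherits(m, "bead_model")))
  to_pa <- function(m) {
    x <- sweep(m$coordinates, 2, colMeans(m$coordinates))
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    R <- ev$vectors
    # deterministic sign: largest-magnitude entry of each axis positive
    for (k in 1:3) {
      j <- which.max(abs(R[, k]))
      if (R[j, k] < 0) R[, k] <- -R[, k]
    }
    if (det(R) < 0) R[, 3] <- -R[, 3]
    m$coordinates <- x %*% R
    m
  }
  out <- lapply(models, to_pa)
  if (length(out) == 1) return(out)
  flips <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  ref <- out[[1]]
  for (i in seq_along(out)[-1]) {
    scores <- vapply(flips, function(f) {
      mm <- out[[i]]
      mm$coordinates <- sweep(mm$coordinates, 2, f, `*`)
      nsd(ref, mm)
    }, numeric(1))
    f <- flips[[which.min(scores)]]
    out[[i]]$coordinates <- sweep(out[[i]]$coordinates, 2, f, `*`)
  }
  out
}

#' Average aligned bead models
#'
#' Builds an occupancy map over the bead positions of all aligned models:
#' each candidate bead's occupancy is the fraction of models having a
#' bead center within one bead radius of it. Beads with occupancy at
#' least `occupancy_cut` are kept and deduplicated (greedy, in input
#' order) so no two kept centers are closer than one bead radius.
#'
#' @param models List of aligned [bead_model()] objects sharing one bead
#'   radius.
#' @param occupancy_cut Minimum occupancy fraction to keep a bead
#'   (default 0.5).
#' @return A [bead_model()] with fractional occupancies.
#' @export
average_models <- function(models, occupancy_cut = 0.5) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  rb <- unique(vapply(models, function(m) m$bead_radius, numeric(1)))
  if (length(rb) != 1)
    stop("models must share one bead radius", call. = FALSE)
  if (length(models) == 1) return(models[[1]])
  all_xyz <- do.call(rbind, lapply(models, function(m) m$coordinates))
  nm <- length(models)
  occ <- vapply(seq_len(nrow(all_xyz)), function(i) {
    p <- all_xyz[i, ]
    hits <- vapply(models, function(m) {
      d2 <- (m$coordinates[, 1] - p[1])^2 + (m$coordinates[, 2] - p[2])^2 +
        (m$coordinates[, 3] - p[3])^2
      any(d2 <= rb^2)
    }, logical(1))
    sum(hits) / nm
  }, numeric(1))
  keep <- which(occ >= occupancy_cut)
  if (!length(keep))
    stop("no beads survive the occupancy cut; lower 'occupancy_cut'",
         call. = FALSE)
  sel <- integer(0)
  for (i in keep) {
    if (!length(sel)) { sel <- i; next }
    d2 <- (all_xyz[sel, 1] - all_xyz[i, 1])^2 +
      (all_xyz[sel, 2] - all_xyz[i, 2])^2 +
      (all_xyz[sel, 3] - all_xyz[i, 3])^2
    if (min(d2) >= rb^2) sel <- c(sel, i)
  }
  bead_model(all_xyz[sel, , drop = FALSE], rb, symmetry = "P1",
             occupancy = occ[sel], tol = rb)
}

#' Normalized spatial discrepancy between bead models
#'
#' Symmetric mean of per-bead nearest-neighbor distances between the two
#' sets, each direction normalized by that set's own mean
#' nearest-neighbor spacing (the bead diameter for single-bead models).
#' Zero for identical models; symmetric in its arguments.
#'
#' @param a,b [bead_model()] objects.
#' @return Nonnegative scalar.
#' @export
nsd <- function(a, b) {
  stopifnot(inherits(a, "bead_model"), inherits(b, "bead_model"))
  spacing <- function(m) {
    n <- nrow(m$coordinates)
    if (n < 2) return(2 * m$bead_radius)
    d <- as.matrix(stats::dist(m$coordinates))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  cross_nn <- function(x, y) {
    vapply(seq_len(nrow(x)), function(i) {
      sqrt(min((y[, 1] - x[i, 1])^2 + (y[, 2] - x[i, 2])^2 +
                 (y[, 3] - x[i, 3])^2))
    }, numeric(1))
  }
  sa <- spacing(a)
  sb <- spacing(b)
  da <- mean(cross_nn(a$coordinates, b$coordinates)) / sa
  db <- mean(cross_nn(b$coordinates, a$coordinates)) / sb
  (da + db) / 2
}

#' Principal-axis extent of a bead model
#'
#' Center-to-center span of the model along its longest principal axis
#' (maximum minus minimum projection of the bead centers).
#'
#' @param model A [bead_model()].
#' @return Extent in Angstrom.
#' @export
bead_extent <- function(model) {
  stopifnot(inherits(model, "bead_model"))
  x <- sweep(model$coordinates, 2, colMeans(model$coordinates))
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  proj <- x %*% ev$vectors[, 1]
  diff(range(proj))
}

#' Read and write bead models as PDB files
#'
#' One dummy CA atom per bead; the occupancy column carries the bead
#' occupancy and the B-factor the bead radius. The files interoperate
#' with standard SAS model viewers.
#'
#' @param model A [bead_model()].
#' @param path File path.
#' @export
write_bead_model <- function(model, path) {
  stopifnot(inherits(model, "bead_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   dummy-atom bead model, radius %.3f A, symmetry %s",
                     model$bead_radius, model$symmetry), con)
  xyz <- model$coordinates
  for (i in seq_len(nrow(xyz))) {
    writeLines(sprintf(
      "ATOM  %5d  CA  DUM A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
      i %% 100000, i %% 10000, xyz[i, 1], xyz[i, 2], xyz[i, 3],
      model$occupancy[i], model$bead_radius), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_bead_model
#' @param symmetry Symmetry tag to attach on read.
#' @export
read_bead_model <- function(path, symmetry = "P1") {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  rb <- at$b[1]
  if (!is.finite(rb) || rb <= 0) rb <- 1
  bead_model(cbind(at$x, at$y, at$z), rb, symmetry = symmetry,
             occupancy = pmin(pmax(at$o, 0), 1), tol = rb)
}
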