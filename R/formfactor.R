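#' Elliptical cylinder model parameters
#'
#' Parameter container for the orientation-averaged elliptical cylinder
#' form factor: minor semi-axis `a` of the elliptical cross-section, the
#' axis ratio nu = major/minor, the cylinder length L, a multiplicative
#' scale (carrying n * drho^2 * V^2 of the absolute intensity in
#' aggregate) and an additive flat background. A supplied axis ratio < 1
#' is renormalized to the equivalent ellipse with nu >= 1.
#'
#' @param minor_radius Minor radius a (Angstrom, > 0).
#' @param axis_ratio Axis ratio nu (>= 1 after normalization).
#' @param length Cylinder length L (Angstrom, > 0).
#' @param scale Multiplicative scale (> 0).
#' @param background Additive constant (>= 0).
#' @return An object of class `ecyl_params`.
#' @export
elliptical_cylinder_params <- function(minor_radius, axis_ratio, length,
                                       scale = 1, background = 0) {
  stopifnot_scalar(minor_radius, "minor_radius")
  stopifnot_scalar(axis_ratio, "axis_ratio")
  stopifnot_scalar(length, "length")
  stopifnot_scalar(scale, "scale")
  if (background < 0) stop("'background' must be >= 0", call. = FALSE)
  if (axis_ratio < 1) {           # same ellipse, swapped axes
    minor_radius <- minor_radius * axis_ratio
    axis_ratio <- 1 / axis_ratio
  }
  structure(list(minor_radius = minor_radius, axis_ratio = axis_ratio,
                 length = length, scale = scale, background = background),
            class = "ecyl_params")
}

#' @export
print.ecyl_params <- function(x, ...) {
  cat(sprintf(
    "Elliptical cylinder: a = %.3f A, nu = %.3f, L = %.2f A, scale = %.4g, bkg = %.4g\n",
    x$minor_radius, x$axis_ratio, x$length, x$scale, x$background))
  invisible(x)
}

#' Geometric radius of gyration of a uniform elliptical cylinder
#'
#' Rg^2 = (a^2 + (nu a)^2) / 4 + L^2 / 12 for a homogeneous cylinder with
#' elliptical cross-section semi-axes a and nu a and length L.
#'
#' @param params An [elliptical_cylinder_params()] object.
#' @return Rg in Angstrom.
#' @export
rg_elliptical_cylinder <- function(params) {
  stopifnot(inherits(params, "ecyl_params"))
  a <- params$minor_radius
  b <- params$axis_ratio * a
  sqrt((a^2 + b^2) / 4 + params$length^2 / 12)
}

#' Sphere form factor
#'
#' Normalized intensity of a homogeneous sphere,
#' I(Q) = (3 (sin(QR) - QR cos(QR)) / (QR)^3)^2, equal to 1 at Q = 0.
#'
#' @param q Scattering-vector grid (1/Angstrom).
#' @param radius Sphere radius (Angstrom, > 0).
#' @return Vector of intensities.
#' @export
intensity_sphere <- function(q, radius) {
  stopifnot_scalar(radius, "radius")
  x <- q * radius
  amp <- ifelse(x < 1e-6, 1 - x^2 / 10,
                3 * (sin(x) - x * cos(x)) / x^3)
  amp^2
}

#' Circular cylinder form factor
#'
#' Orientation-averaged normalized intensity of a homogeneous circular
#' cylinder of radius R and length L: a single quadrature over the axis
#' tilt with the cross-section factor (2 J1(t)/t)^2 and the longitudinal
#' factor (sin(u)/u)^2.
#'
#' @param q Scattering-vector grid (1/Angstrom).
#' @param radius Cross-section radius (Angstrom).
#' @param length Cylinder length (Angstrom).
#' @param n_points Gauss-Legendre quadrature order (default 76).
#' @return Vector of intensities, normalized to 1 at Q = 0.
#' @export
intensity_cylinder <- function(q, radius, length, n_points = 76) {
  stopifnot_scalar(radius, "radius")
  stopifnot_scalar(length, "length")
  if (n_points < 8) stop("quadrature order too small", call. = FALSE)
  gl <- gauss_legendre(n_points, 0, 1)
  out <- numeric(base::length(q))
  for (k in seq_along(gl$x)) {
    x <- gl$x[k]
    u <- q * length * x / 2
    t <- q * radius * sqrt(1 - x^2)
    lam <- ifelse(t < 1e-8, 1, 2 * besselJ(pmax(t, 1e-12), 1) / t)
    out <- out + gl$w[k] * lam^2 * sinc(u)^2
  }
  out
}

#' Elliptical cylinder form factor
#'
#' Orientation-averaged normalized intensity of a homogeneous cylinder
#' with elliptical cross-section (semi-axes a and nu a, length L), via a
#' double Gauss-Legendre quadrature: outer over the axis tilt x in `[0,1]`
#' with the longitudinal factor (sin(u)/u)^2 at u = Q L x / 2, inner over
#' the cross-section azimuth y in `[0, pi]` with the cross-section kernel
#' Lambda1(t) = 2 J1(t)/t (cylindrical first-order Bessel function)
#' evaluated at the effective radius
#' a sqrt((1 + nu^2)/2 + (1 - nu^2)/2 cos(y)). The result is multiplied
#' by `scale` and offset by `background`; the bare form factor is
#' normalized to 1 at Q = 0.
#'
#' @param q Scattering-vector grid (1/Angstrom).
#' @param params An [elliptical_cylinder_params()] object.
#' @param n_points Gauss-Legendre order per axis (default 76).
#' @return Vector of intensities.
#' @examples
#' p <- elliptical_cylinder_params(14.64, 2.07, 73)
#' q <- seq(0.005, 0.25, length.out = 100)
#' i <- intensity_elliptical_cylinder(q, p)
#' @export
intensity_elliptical_cylinder <- function(q, params, n_points = 76) {
  stopifnot(inherits(params, "ecyl_params"))
  if (n_points < 8) stop("quadrature order too small", call. = FALSE)
  a <- params$minor_radius
  nu <- params$axis_ratio
  L <- params$length
  gx <- gauss_legendre(n_points, 0, 1)
  gy <- gauss_legendre(n_points, 0, pi)
  reff <- a * sqrt((1 + nu^2) / 2 + (1 - nu^2) / 2 * cos(gy$x))
  out <- numeric(length(q))
  for (k in seq_along(gx$x)) {
    x <- gx$x[k]
    u <- q * L * x / 2
    tmat <- outer(q * sqrt(1 - x^2), reff)     # n_q x n_y
    lam <- ifelse(tmat < 1e-8, 1, 2 * besselJ(pmax(tmat, 1e-12), 1) / tmat)
    psi <- as.vector(lam^2 %*% gy$w) / pi
    out <- out + gx$w[k] * psi * sinc(u)^2
  }
  params$scale * out + params$background
}

# model registry for fit_model: par vectors <-> intensity functions
.ff_models <- function(model, fit_background) {
  switch(model,
    sphere = list(
      par_names = c("radius", "scale", if (fit_background) "background"),
      fun = function(q, p, n_points)
        p[["scale"]] * intensity_sphere(q, p[["radius"]]) +
          (if (fit_background) p[["background"]] else 0)),
    cylinder = list(
      par_names = c("radius", "length", "scale",
                    if (fit_background) "background"),
      fun = function(q, p, n_points)
        p[["scale"]] * intensity_cylinder(q, p[["radius"]], p[["length"]],
                                          n_points) +
          (if (fit_background) p[["background"]] else 0)),
    elliptical_cylinder = list(
      par_names = c("minor_radius", "axis_ratio", "length", "scale",
                    if (fit_background) "background"),
      fun = function(q, p, n_points)
        intensity_elliptical_cylinder(q,
          elliptical_cylinder_params(p[["minor_radius"]], p[["axis_ratio"]],
                                     p[["length"]], p[["scale"]],
                                     if (fit_background) p[["background"]] else 0),
          n_points)),
    stop("unknown model: ", model, call. = FALSE))
}

#' Fit an analytic form-factor model to a scattering curve
#'
#' Bounded weighted least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) minimizing sum(((I_data - I_model)/sigma)^2). The
#' model curve is optionally smeared through the instrumental resolution
#' before comparison. The fit is deterministic given the initial values.
#'
#' @param curve A [scattering_curve()] with uncertainties.
#' @param model One of `"sphere"`, `"cylinder"`,
#'   `"elliptical_cylinder"`.
#' @param init Named numeric vector of initial parameter values.
#' @param lower,upper Named numeric vectors of bounds (defaults: positive
#'   parameters bounded below by tiny values, unbounded above).
#' @param fit_background Fit an additive flat background (default FALSE;
#'   background fixed at 0).
#' @param resolution Optional [resolution_spec()] applied to the model.
#' @param n_points Quadrature order for cylinder models.
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `sas_fit`: `params` (named vector),
#'   `uncertainties` (1-sigma, from the scaled covariance of the fit),
#'   `reduced_chi2`, `n_points`, `model`, `fitted` (model curve on the
#'   data grid).
#' @export
fit_model <- function(curve, model, init, lower = NULL, upper = NULL,
                      fit_background = FALSE, resolution = NULL,
                      n_points = 76, max_iter = 100) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (is.null(curve$sigma))
    stop("'curve' must carry uncertainties for weighted fitting",
         call. = FALSE)
  spec <- .ff_models(model, fit_background)
  pn <- spec$par_names
  if (!all(pn %in% names(init)))
    stop("missing initial values for: ",
         paste(setdiff(pn, names(init)), collapse = ", "), call. = FALSE)
  init <- init[pn]
  lo <- stats::setNames(rep(1e-6, length(pn)), pn)
  if (fit_background) lo["background"] <- 0
  hi <- stats::setNames(rep(Inf, length(pn)), pn)
  if ("axis_ratio" %in% pn) lo["axis_ratio"] <- 1
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(init < lo[pn] | init > hi[pn]))
    stop("initial values outside bounds", call. = FALSE)
  residfun <- function(p) {
    p <- stats::setNames(p, pn)
    m <- spec$fun(curve$q, as.list(p), n_points)
    if (!is.null(resolution))
      m <- smear_resolution(scattering_curve(curve$q, m), resolution)$intensity
    (curve$intensity - m) / curve$sigma
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lo[pn], upper = hi[pn],
                            fn = residfun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter))
  if (fit$info == 0 || fit$info == 9) {
    e <- simpleError(
      sprintf("form-factor fit did not converge (info %d)", fit$info))
    e$best_params <- stats::setNames(fit$par, pn)
    stop(e)
  }
  p <- stats::setNames(as.numeric(fit$par), pn)
  nq <- length(curve$q)
  dof <- max(nq - length(p), 1)
  red_chi2 <- fit$deviance / dof
  unc <- tryCatch({
    cov <- solve(fit$hessian) * red_chi2
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) rep(NA_real_, length(p)))
  m <- spec$fun(curve$q, as.list(p), n_points)
  if (!is.null(resolution))
    m <- smear_resolution(scattering_curve(curve$q, m), resolution)$intensity
  structure(list(params = p,
                 uncertainties = stats::setNames(unc, pn),
                 reduced_chi2 = red_chi2,
                 n_points = nq,
                 model = model,
                 fitted = m),
            class = "sas_fit")
}

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("Form-factor fit: %s (%d points)\n", x$model, x$n_points))
  for (nm in names(x$params))
    cat(sprintf("  %-13s %.5g +/- %.3g\n", nm, x$params[[nm]],
                x$uncertainties[[nm]]))
  cat(sprintf("  reduced chi^2 = %.4g\n", x$reduced_chi2))
  invisible(x)
}

#' @export
coef.sas_fit <- function(object, ...) object$params
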