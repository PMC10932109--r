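#' Elution component
#'
#' One species eluting from the SEC column: its noise-free reference
#' scattering curve, the Gaussian elution-peak center and width (in frame
#' units), and an amplitude scaling the concentration at the peak.
#'
#' @param reference_curve A noise-free [scattering_curve()].
#' @param peak_center Elution peak center (frame index).
#' @param peak_width Gaussian sigma of the elution peak (frames, > 0).
#' @param amplitude Peak concentration scale (>= 0).
#' @return An object of class `elution_component`.
#' @export
elution_component <- function(reference_curve, peak_center, peak_width,
                              amplitude = 1) {
  stopifnot(inherits(reference_curve, "scattering_curve"))
  stopifnot_scalar(peak_width, "peak_width")
  if (amplitude < 0) stop("'amplitude' must be >= 0", call. = FALSE)
  structure(list(reference_curve = reference_curve,
                 peak_center = peak_center, peak_width = peak_width,
                 amplitude = amplitude),
            class = "elution_component")
}

#' Reference components for the two-fraction study geometry
#'
#' Builds the noise-free component curves of a two-species elution: an
#' elongated high molecular weight particle eluting first and a more
#' compact low molecular weight particle eluting later. The `"table1"`
#' geometry set uses elliptical cylinders with minor radius 13.49 A,
#' axis ratio 2.06, length 100 A (high MW) and minor radius 14.64 A,
#' axis ratio 2.07, length 73 A (low MW), forward intensities 0.075 and
#' 0.072, smeared through the instrumental resolution on the instrument
#' grid Q = 0.03-0.25 1/Angstrom.
#'
#' @param geometry_set Identifier; only `"table1"` is defined.
#' @param q Q grid (default 90 points over 0.03-0.25 1/Angstrom).
#' @param resolution A [resolution_spec()] (default 6 A +/- 10%).
#' @param i0 Length-2 named numeric `c(high = , low = )` forward
#'   intensities.
#' @param centers,widths Elution peak centers and Gaussian widths
#'   (frames) for the high and low MW components.
#' @return A list with elements `high_mw` and `low_mw`, each an
#'   [elution_component()].
#' @export
make_reference_components <- function(geometry_set = "table1", q = NULL,
                                      resolution = resolution_spec(),
                                      i0 = c(high = 0.075, low = 0.072),
                                      centers = c(high = 18, low = 36),
                                      widths = c(high = 4, low = 5)) {
  if (!identical(geometry_set, "table1"))
    stop("unknown geometry set: ", geometry_set, call. = FALSE)
  q <- q %||% seq(0.03, 0.25, length.out = 90)
  geo <- list(
    high = elliptical_cylinder_params(13.49, 2.06, 100, scale = i0[["high"]]),
    low  = elliptical_cylinder_params(14.64, 2.07, 73,  scale = i0[["low"]]))
  mk <- function(which) {
    i <- intensity_elliptical_cylinder(q, geo[[which]])
    crv <- smear_resolution(
      scattering_curve(q, i, label = paste0(which, "_mw_reference")),
      resolution)
    elution_component(crv, centers[[which]], widths[[which]], amplitude = 1)
  }
  list(high_mw = mk("high"), low_mw = mk("low"))
}

#' Simulate a SEC-SANS run
#'
#' Each frame's noise-free intensity is the sum over components of
#' amplitude x exp(-(f - center)^2 / (2 width^2)) x reference(q), plus a
#' flat buffer background. Observed intensities add Gaussian noise with
#' sigma = noise_scale * sqrt(noise-free intensity), the Gaussian
#' approximation to counting statistics; the per-point sigma is stored.
#' All randomness flows from `seed`.
#'
#' @param components List of [elution_component()] objects sharing one
#'   Q grid.
#' @param n_frames Number of 30 s exposure frames (>= 10).
#' @param background_level Flat buffer counts level.
#' @param noise_scale Noise amplitude (>= 0); 0 gives noise-free frames.
#' @param seed RNG seed.
#' @param exposure Exposure seconds per frame (metadata).
#' @return An object of class `secsans_run`: `q`, `frames` (intensity
#'   matrix, n_q x n_frames), `sigma` (same shape), `elution` (frame
#'   indices), `components`, `background_level`, `noise_scale`, `seed`,
#'   `exposure`.
#' @export
simulate_run <- function(components, n_frames = 60,
                         background_level = 0.002, noise_scale = 0.005,
                         seed = 1, exposure = 30) {
  if (!length(components)) stop("need at least one component", call. = FALSE)
  lapply(components, function(cc)
    stopifnot(inherits(cc, "elution_component")))
  if (n_frames < 10) stop("'n_frames' must be >= 10", call. = FALSE)
  if (noise_scale < 0) stop("'noise_scale' must be >= 0", call. = FALSE)
  q <- components[[1]]$reference_curve$q
  for (cc in components)
    if (!isTRUE(all.equal(cc$reference_curve$q, q)))
      stop("components must share one Q grid", call. = FALSE)
  nq <- length(q)
  clean <- matrix(background_level, nq, n_frames)
  for (cc in components) {
    prof <- cc$amplitude *
      exp(-(seq_len(n_frames) - cc$peak_center)^2 / (2 * cc$peak_width^2))
    clean <- clean + outer(cc$reference_curve$intensity, prof)
  }
  sig <- noise_scale * sqrt(pmax(clean, 0))
  set.seed(seed)
  obs <- clean + matrix(stats::rnorm(nq * n_frames), nq, n_frames) * sig
  if (noise_scale == 0) sig[] <- 1e-12   # stored sigma must stay positive
  structure(list(q = q, frames = obs, sigma = sig,
                 elution = seq_len(n_frames),
                 components = components,
                 background_level = background_level,
                 noise_scale = noise_scale, seed = seed,
                 exposure = exposure),
            class = "secsans_run")
}

#' @export
print.secsans_run <- function(x, ...) {
  cat(sprintf(
    "SEC-SANS run: %d frames x %d Q points, %d component(s), seed %d\n",
    ncol(x$frames), length(x$q), length(x$components), x$seed))
  invisible(x)
}

#' Scattergram: total intensity per elution frame
#'
#' Sums the background-subtracted intensity of every frame over a Q
#' window (default: the full range) and locates elution peaks as local
#' maxima whose topographic prominence exceeds a threshold. The default
#' threshold adapts to the series: the largest of 15% of the series
#' maximum, 8 x the median propagated frame uncertainty, and 6 x the
#' frame-to-frame noise level (median absolute successive difference /
#' sqrt(2)), so a flat noise-only series yields no peaks.
#'
#' @param run A [simulate_run()] result.
#' @param q_window Optional length-2 `c(lo, hi)` Q window.
#' @param prominence Optional absolute prominence threshold.
#' @return An object of class `scattergram`: `frame`, `total`, `peaks`
#'   (frame indices of detected peaks), `prominences`.
#' @export
scattergram <- function(run, q_window = NULL, prominence = NULL) {
  stopifnot(inherits(run, "secsans_run"))
  sel <- if (is.null(q_window)) seq_along(run$q)
         else which(run$q >= q_window[1] & run$q <= q_window[2])
  if (!length(sel)) stop("empty Q window", call. = FALSE)
  total <- colSums(run$frames[sel, , drop = FALSE] - run$background_level)
  n <- length(total)
  noise <- stats::mad(diff(total)) / sqrt(2)
  sig_tot <- sqrt(colSums(run$sigma[sel, , drop = FALSE]^2))
  thr <- prominence %||% max(0.15 * max(total, 0),
                             8 * stats::median(sig_tot), 6 * noise, 1e-12)
  is_max <- which(vapply(seq_len(n), function(i) {
    lo <- max(1, i - 1); hi <- min(n, i + 1)
    total[i] >= max(total[lo:hi]) && (i > 1 && i < n)
  }, logical(1)))
  prom <- vapply(is_max, function(i) {
    higher <- which(total > total[i])
    lv <- higher[higher < i]; rv <- higher[higher > i]
    left_min <- if (length(lv)) min(total[(max(lv) + 1):i]) else min(total[1:i])
    right_min <- if (length(rv)) min(total[i:(min(rv) - 1)]) else min(total[i:n])
    total[i] - max(left_min, right_min)
  }, numeric(1))
  keep <- prom >= thr
  structure(list(frame = seq_len(n), total = total,
                 peaks = is_max[keep], prominences = prom[keep],
                 threshold = thr),
            class = "scattergram")
}

#' @export
print.scattergram <- function(x, ...) {
  cat(sprintf("Scattergram: %d frames, %d peak(s) at frame(s): %s\n",
              length(x$frame), length(x$peaks),
              paste(x$peaks, collapse = ", ")))
  invisible(x)
}

#' @export
plot.scattergram <- function(x, ...) {
  graphics::plot(x$frame, x$total, type = "b", xlab = "frame",
                 ylab = "total intensity", ...)
  graphics::abline(v = x$peaks, col = 2, lty = 2)
  invisible(x)
}

#' Frame ranges around detected elution peaks
#'
#' For each detected peak, a Gaussian is fitted locally (ln total versus
#' frame, quadratic, over points above 30% of the peak height) and the
#' range |frame - center| <= `n_sigma` x sigma is returned.
#'
#' @param sg A [scattergram()].
#' @param n_sigma Half-width of the range in fitted sigmas (default 1).
#' @return A list of integer frame vectors, one per peak.
#' @export
peak_frame_ranges <- function(sg, n_sigma = 1) {
  stopifnot(inherits(sg, "scattergram"))
  lapply(sg$peaks, function(p) {
    h <- sg$total[p]
    lo <- p
    while (lo > 1 && sg$total[lo - 1] > 0.3 * h &&
           sg$total[lo - 1] < sg$total[lo]) lo <- lo - 1
    hi <- p
    n <- length(sg$total)
    while (hi < n && sg$total[hi + 1] > 0.3 * h &&
           sg$total[hi + 1] < sg$total[hi]) hi <- hi + 1
    idx <- lo:hi
    y <- log(pmax(sg$total[idx], 1e-12 * h))
    cf <- stats::coef(stats::lm(y ~ idx + I(idx^2)))
    sd_fit <- if (is.finite(cf[3]) && cf[3] < 0) sqrt(-1 / (2 * cf[3]))
              else (hi - lo + 1) / 4
    ctr <- if (is.finite(cf[3]) && cf[3] < 0) -cf[2] / (2 * cf[3]) else p
    rng <- seq.int(max(1, floor(ctr - n_sigma * sd_fit)),
                   min(n, ceiling(ctr + n_sigma * sd_fit)))
    rng
  })
}

#' Average frames into a fraction curve
#'
#' Inverse-variance weighted mean per Q point over the selected frames
#' after background subtraction; the pooled sigma is the inverse-variance
#' combination, shrinking as sqrt(n) for identical frames.
#'
#' @param run A [simulate_run()] result.
#' @param frame_range Integer vector of frame indices.
#' @param label Optional label for the averaged curve.
#' @return A [scattering_curve()] with uncertainties.
#' @export
average_peak <- function(run, frame_range, label = NULL) {
  stopifnot(inherits(run, "secsans_run"))
  frame_range <- as.integer(frame_range)
  if (!length(frame_range)) stop("empty frame range", call. = FALSE)
  if (any(frame_range < 1 | frame_range > ncol(run$frames)))
    stop("frame range outside the run", call. = FALSE)
  I <- run$frames[, frame_range, drop = FALSE] - run$background_level
  S <- run$sigma[, frame_range, drop = FALSE]
  w <- 1 / S^2
  sw <- rowSums(w)
  scattering_curve(run$q, rowSums(w * I) / sw, sqrt(1 / sw),
                   label = label %||% sprintf("frames %d-%d",
                                              min(frame_range),
                                              max(frame_range)))
}

#' Persist and reload a SEC-SANS run
#'
#' `write_run` stores per-frame curves as 3-column text files plus a JSON
#' manifest (component configuration, background, noise scale, seed);
#' `read_run` reconstructs the run from such a directory.
#'
#' @param run A [simulate_run()] result.
#' @param dir Directory path (created if needed).
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "secsans_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- ncol(run$frames)
  files <- sprintf("frame_%03d.dat", seq_len(nf))
  for (k in seq_len(nf))
    write_curve(scattering_curve(run$q, run$frames[, k], run$sigma[, k]),
                file.path(dir, files[k]))
  comp <- lapply(run$components, function(cc) {
    f <- sprintf("component_%s.dat",
                 gsub("[^A-Za-z0-9_]", "_",
                      cc$reference_curve$label %||% "ref"))
    write_curve(cc$reference_curve, file.path(dir, f))
    list(file = f, peak_center = cc$peak_center,
         peak_width = cc$peak_width, amplitude = cc$amplitude,
         label = cc$reference_curve$label)
  })
  manifest <- list(frames = files, elution = run$elution,
                   components = comp,
                   background_level = run$background_level,
                   noise_scale = run$noise_scale, seed = run$seed,
                   exposure = run$exposure)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  frames <- lapply(file.path(dir, mf$frames), read_curve)
  q <- frames[[1]]$q
  comps_raw <- mf$components
  if (is.data.frame(comps_raw))
    comps_raw <- lapply(seq_len(nrow(comps_raw)),
                        function(i) as.list(comps_raw[i, ]))
  comps <- lapply(comps_raw, function(cc)
    elution_component(read_curve(file.path(dir, cc$file), label = cc$label),
                      cc$peak_center, cc$peak_width, cc$amplitude))
  structure(list(q = q,
                 frames = vapply(frames, function(f) f$intensity,
                                 numeric(length(q))),
                 sigma = vapply(frames, function(f) f$sigma,
                                numeric(length(q))),
                 elution = mf$elution,
                 components = comps,
                 background_level = mf$background_level,
                 noise_scale = mf$noise_scale, seed = mf$seed,
                 exposure = mf$exposure),
            class = "secsans_run")
}
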