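#' Scattering curve container
#'
#' A `scattering_curve` holds a one-dimensional small-angle scattering
#' profile: the modulus of the scattering vector Q = 4 pi sin(theta) / lambda
#' (theta being half the scattering angle), the measured or modelled
#' intensity I(Q) (differential cross-section per unit volume), and optional
#' 1-sigma uncertainties. It is the common currency passed between all
#' analysis stages.
#'
#' @param q Numeric vector of scattering-vector magnitudes (1/Angstrom),
#'   strictly increasing and positive.
#' @param intensity Numeric vector of intensities, same length as `q`,
#'   finite everywhere.
#' @param sigma Optional numeric vector of 1-sigma uncertainties, strictly
#'   positive where present.
#' @param label Optional free-text label.
#' @return An object of class `scattering_curve` with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`) and `label`.
#' @examples
#' crv <- scattering_curve(seq(0.01, 0.25, 0.005),
#'                         exp(-seq(0.01, 0.25, 0.005)^2 * 300))
#' print(crv)
#' @export
scattering_curve <- function(q, intensity, sigma = NULL, label = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("'q' and 'intensity' must have equal length", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0))
    stop("'q' must be finite and > 0 everywhere", call. = FALSE)
  if (any(diff(q) <= 0))
    stop("'q' must be strictly increasing", call. = FALSE)
  if (any(!is.finite(intensity)))
    stop("'intensity' must be finite everywhere", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("'sigma' must have the same length as 'q'", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("'sigma' must be finite and > 0 everywhere", call. = FALSE)
  }
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = label),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat("Scattering curve", if (!is.null(x$label)) paste0("'", x$label, "'"),
      "\n")
  cat(sprintf("  %d points, Q = %.4g .. %.4g 1/A, %s uncertainties\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "no" else "with"))
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$q)

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

#' @export
plot.scattering_curve <- function(x, log = "y", ...) {
  graphics::plot(x$q, x$intensity, log = log, xlab = "Q (1/A)",
                 ylab = "I(Q)", main = x$label %||% "", ...)
  invisible(x)
}

#' Read and write scattering curves as 3-column text
#'
#' Whitespace-delimited columns Q, I and (optionally) sigma; lines starting
#' with `#` are comments. This is the de-facto exchange format of
#' small-angle scattering software.
#'
#' @param path File path.
#' @param label Optional label attached to the curve on read (defaults to
#'   the file name).
#' @return `read_curve` returns a [scattering_curve()].
#' @export
read_curve <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("q", "i", "sigma")[1:3],
                         fill = TRUE, header = FALSE)
  if (ncol(d) < 2) stop("expected at least 2 columns in ", path, call. = FALSE)
  # an all-zero third column is the writer's "no uncertainties" placeholder
  sigma <- if (ncol(d) >= 3 && !all(is.na(d[[3]])) && any(d[[3]] != 0))
    d[[3]] else NULL
  scattering_curve(d[[1]], d[[2]], sigma, label = label %||% basename(path))
}

#' @rdname read_curve
#' @param curve A [scattering_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", curve$label %||% "scattering curve"), con)
  writeLines("# Q (1/A)  I(Q)  sigma", con)
  s <- curve$sigma %||% rep(0, length(curve$q))
  writeLines(sprintf("%.8e %.8e %.8e", curve$q, curve$intensity, s), con)
  invisible(path)
}

#' Rebin a curve to a smaller number of Q bins
#'
#' Points are grouped into `n_bins` contiguous bins of (as near as possible)
#' equal point count. Within each bin the intensity is averaged with
#' inverse-variance weights, the pooled sigma is the inverse-variance
#' combination, and the bin Q is the plain mean of member Q values. Without
#' uncertainties a plain mean is used.
#'
#' @param curve A [scattering_curve()].
#' @param n_bins Number of output bins, at most the number of points.
#' @return A rebinned [scattering_curve()].
#' @export
rebin_curve <- function(curve, n_bins) {
  stopifnot(inherits(curve, "scattering_curve"))
  n_bins <- as.integer(n_bins)
  n <- length(curve$q)
  if (n_bins < 1L) stop("'n_bins' must be >= 1", call. = FALSE)
  if (n_bins > n)
    stop(sprintf("'n_bins' (%d) exceeds the number of points (%d)",
                 n_bins, n), call. = FALSE)
  grp <- ceiling(seq_len(n) / (n / n_bins))
  grp <- pmin(grp, n_bins)
  qs <- tapply(curve$q, grp, mean)
  if (is.null(curve$sigma)) {
    is_ <- tapply(curve$intensity, grp, mean)
    ss <- NULL
  } else {
    w <- 1 / curve$sigma^2
    sw <- tapply(w, grp, sum)
    is_ <- tapply(w * curve$intensity, grp, sum) / sw
    ss <- sqrt(1 / sw)
  }
  scattering_curve(as.numeric(qs), as.numeric(is_),
                   if (is.null(ss)) NULL else as.numeric(ss),
                   label = curve$label)
}
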