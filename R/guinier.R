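#' Guinier analysis of the low-Q region
#'
#' At small Q the intensity of a dilute, monodisperse particle follows the
#' Guinier law I(Q) = I(0) exp(-Q^2 Rg^2 / 3). A weighted least-squares
#' fit of ln I versus Q^2 over a low-Q window therefore yields the radius
#' of gyration Rg = sqrt(-3 slope) and the forward scattering
#' I(0) = exp(intercept). Weights follow from error propagation of the
#' logarithm, sigma_lnI = sigma / I; the fit is unweighted when the curve
#' carries no uncertainties.
#'
#' The window may be given explicitly (`window`, an index range), as a
#' Q*Rg band (`qrg_window`, resolved self-consistently so that the quoted
#' bounds hold at the fitted Rg), or left `NULL`, in which case
#' [auto_window()] selects it.
#'
#' @param curve A [scattering_curve()].
#' @param window Optional integer vector of point indices to fit.
#' @param qrg_window Optional length-2 numeric `c(lo, hi)`: fit points with
#'   lo < Q*Rg < hi at the self-consistent Rg.
#' @param qrg_limit Upper Q*Rg cap passed to [auto_window()] when no window
#'   is given.
#' @return An object of class `guinier_fit` with elements `rg`, `i0`,
#'   `window`, `qrg_bounds`, `fit_quality` (R^2 of the linear fit), and
#'   `rg_se`/`i0_se` when uncertainties are available.
#' @examples
#' q <- seq(0.01, 0.2, 0.002)
#' crv <- scattering_curve(q, 2.5 * exp(-q^2 * 30^2 / 3))
#' fit_guinier(crv)
#' @export
fit_guinier <- function(curve, window = NULL, qrg_window = NULL,
                        qrg_limit = 1.3) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (is.null(window) && is.null(qrg_window))
    window <- auto_window(curve, qrg_limit)
  if (!is.null(qrg_window)) {
    stopifnot(length(qrg_window) == 2, qrg_window[1] < qrg_window[2])
    window <- guinier_qrg_window(curve, qrg_window[1], qrg_window[2])
  }
  guinier_fit_window(curve, window)
}

# weighted ln-linear fit over a fixed index window
guinier_fit_window <- function(curve, window) {
  window <- sort(unique(as.integer(window)))
  n <- length(curve$q)
  if (any(window < 1L | window > n))
    stop("window indices outside the curve", call. = FALSE)
  if (length(window) < 5)
    stop("Guinier window must contain at least 5 points", call. = FALSE)
  q <- curve$q[window]
  i <- curve$intensity[window]
  if (any(i <= 0))
    stop("nonpositive intensity inside the Guinier window", call. = FALSE)
  x <- q^2
  y <- log(i)
  if (!is.null(curve$sigma)) {
    w <- (i / curve$sigma[window])^2
    fit <- stats::lm(y ~ x, weights = w)
  } else {
    w <- rep(1, length(x))
    fit <- stats::lm(y ~ x)
  }
  cf <- stats::coef(fit)
  if (cf[2] >= 0)
    stop("positive slope: no Guinier regime in the selected window",
         call. = FALSE)
  rg <- sqrt(-3 * cf[2])
  i0 <- exp(cf[1])
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  r2 <- {
    res <- stats::residuals(fit)
    1 - sum(w * res^2) / sum(w * (y - stats::weighted.mean(y, w))^2)
  }
  structure(list(rg = unname(rg), i0 = unname(i0),
                 rg_se = unname(3 * se[2] / (2 * rg)),
                 i0_se = unname(i0 * se[1]),
                 window = window,
                 qrg_bounds = c(q[1] * rg, q[length(q)] * rg),
                 fit_quality = r2,
                 n_points = length(window)),
            class = "guinier_fit")
}

# resolve a QRg band into an index window, self-consistently in Rg
guinier_qrg_window <- function(curve, qrg_lo, qrg_hi, max_iter = 100) {
  q <- curve$q
  pos <- which(curve$intensity > 0)
  if (length(pos) < 10)
    stop("too few positive-intensity points for Guinier analysis",
         call. = FALSE)
  # seed Rg from the leading positive points
  seed <- pos[seq_len(min(10, length(pos)))]
  cf <- stats::coef(stats::lm(log(curve$intensity[seed]) ~ I(q[seed]^2)))
  rg <- if (cf[2] < 0) sqrt(-3 * cf[2]) else 1 / q[seed[5]]
  window <- NULL
  for (it in seq_len(max_iter)) {
    sel <- pos[q[pos] * rg > qrg_lo & q[pos] * rg < qrg_hi]
    if (length(sel) < 5)
      stop("fewer than 5 points satisfy the requested Q*Rg band",
           call. = FALSE)
    f <- guinier_fit_window(curve, sel)
    if (!is.null(window) && identical(sel, window)) break
    window <- sel
    rg <- f$rg
  }
  window
}

#' Automatic Guinier window selection
#'
#' Starting from the first positive-intensity point, leading points are
#' dropped one at a time as long as doing so improves the goodness of the
#' ln-linear fit, and the upper edge of the window is capped so that
#' Q * Rg <= `qrg_limit` at the self-consistent Rg. The procedure is
#' deterministic. Low-Q contamination (aggregates, inter-particle effects)
#' confined to the first points is excluded by the leading-point drop.
#'
#' @param curve A [scattering_curve()].
#' @param qrg_limit Upper bound on Q*Rg for the window (default 1.3, the
#'   conventional validity limit of the Guinier expansion for globular
#'   particles).
#' @return An integer vector of point indices.
#' @export
auto_window <- function(curve, qrg_limit = 1.3) {
  stopifnot(inherits(curve, "scattering_curve"))
  if (qrg_limit <= 0) stop("'qrg_limit' must be > 0", call. = FALSE)
  q <- curve$q
  pos <- which(curve$intensity > 0)
  fit_from <- function(start_idx) {
    # self-consistent upper cap at Q*Rg <= qrg_limit
    cand <- pos[pos >= start_idx]
    if (length(cand) < 5) return(NULL)
    seed <- cand[seq_len(min(10, length(cand)))]
    cf <- stats::coef(stats::lm(log(curve$intensity[seed]) ~ I(q[seed]^2)))
    if (cf[2] >= 0) return(NULL)
    rg <- sqrt(-3 * cf[2])
    win <- NULL
    for (it in 1:100) {
      sel <- cand[q[cand] * rg <= qrg_limit]
      if (length(sel) < 5) return(NULL)
      f <- tryCatch(guinier_fit_window(curve, sel), error = function(e) NULL)
      if (is.null(f)) return(NULL)
      if (!is.null(win) && identical(sel, win)) return(list(window = sel, fit = f))
      win <- sel
      rg <- f$rg
    }
    list(window = win, fit = f)
  }
  # first usable start: skip leading starts where no self-consistent
  # window exists (heavy contamination can push the seed Rg out of range)
  k <- 1
  best <- NULL
  while (is.null(best) && k <= length(pos) - 4) {
    best <- fit_from(pos[k])
    if (is.null(best)) k <- k + 1
  }
  if (is.null(best))
    stop("no Guinier window with >= 5 points satisfies the Q*Rg cap",
         call. = FALSE)
  while (k < length(pos)) {
    nxt <- fit_from(pos[k + 1])
    if (is.null(nxt) || nxt$fit$fit_quality <= best$fit$fit_quality) break
    best <- nxt
    k <- k + 1
  }
  best$window
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat("Guinier fit\n")
  cat(sprintf("  Rg   = %.3f A%s\n", x$rg,
              if (!is.null(x$rg_se) && is.finite(x$rg_se))
                sprintf(" +/- %.3f", x$rg_se) else ""))
  cat(sprintf("  I(0) = %.4g\n", x$i0))
  cat(sprintf("  window: %d points, %.2f < Q*Rg < %.2f, R^2 = %.4f\n",
              x$n_points, x$qrg_bounds[1], x$qrg_bounds[2], x$fit_quality))
  invisible(x)
}

#' @export
coef.guinier_fit <- function(object, ...) {
  c(rg = object$rg, i0 = object$i0)
}
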