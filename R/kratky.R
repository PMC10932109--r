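#' Kratky profile and compactness classification
#'
#' The Kratky representation Q^2 I(Q) versus Q discriminates folded from
#' unfolded chains: a compact, globular particle shows a bell-shaped,
#' nearly Gaussian peak that decays at high Q, while a flexible
#' (Gaussian-chain-like) particle approaches a non-decaying plateau.
#'
#' The classification is deterministic given the profile and thresholds:
#' the curve is `folded` when it rises to an interior maximum that exceeds
#' `peak_ratio` times the median of the final third of the profile (the
#' high-Q tail), `unfolded` when the final third is a plateau (its fitted
#' slope, normalized by the tail level over the tail span, is within
#' `plateau_tol` of zero), and `indeterminate` otherwise. Curves with fewer
#' than 10 points are `indeterminate` with a warning.
#'
#' @param curve A [scattering_curve()].
#' @param peak_ratio Peak-to-tail ratio required to call `folded`
#'   (default 1.5).
#' @param plateau_tol Relative slope tolerance for the high-Q plateau
#'   (default 0.05).
#' @return An object of class `kratky_profile` with elements `q`, `q2i`
#'   and `classification`.
#' @export
compute_kratky <- function(curve, peak_ratio = 1.5, plateau_tol = 0.05) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q
  q2i <- q^2 * curve$intensity
  n <- length(q)
  cls <- "indeterminate"
  if (n < 10) {
    warning("fewer than 10 points: Kratky classification is indeterminate")
  } else {
    tail_idx <- seq.int(ceiling(2 * n / 3), n)
    tail_med <- stats::median(q2i[tail_idx])
    imax <- which.max(q2i)
    interior <- imax > 1 && imax < tail_idx[1]
    peak_ok <- interior && tail_med > 0 &&
      q2i[imax] >= peak_ratio * tail_med
    # also accept an interior peak decaying towards a ~zero tail
    peak_ok <- peak_ok || (interior && tail_med <= 0 && q2i[imax] > 0)
    sl <- stats::coef(stats::lm(q2i[tail_idx] ~ q[tail_idx]))[2]
    span <- q[n] - q[tail_idx[1]]
    rel_slope <- sl * span / max(abs(tail_med), 1e-300)
    if (peak_ok) {
      cls <- "folded"
    } else if (is.finite(rel_slope) && abs(rel_slope) <= plateau_tol) {
      cls <- "unfolded"
    }
  }
  structure(list(q = q, q2i = q2i, classification = cls),
            class = "kratky_profile")
}

#' @export
print.kratky_profile <- function(x, ...) {
  cat(sprintf("Kratky profile: %d points, classification: %s\n",
              length(x$q), x$classification))
  invisible(x)
}

#' @export
plot.kratky_profile <- function(x, ...) {
  graphics::plot(x$q, x$q2i, type = "l", xlab = "Q (1/A)",
                 ylab = expression(Q^2 * I(Q)),
                 main = paste("Kratky:", x$classification), ...)
  invisible(x)
}
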