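#' Pipeline configuration
#'
#' Parameters for the full per-fraction analysis: Guinier window cap,
#' Dmax scan candidates, r-grid size, the Q cut applied to reconstruction
#' inputs, elliptical-cylinder fit initialization, and reconstruction
#' settings (off by default; 5 runs with coarse beads when enabled, 20
#' runs being the full-scale protocol).
#'
#' @param qrg_limit Guinier window Q*Rg cap.
#' @param dmax_candidates Candidate Dmax values (Angstrom) for the scan.
#' @param n_r P(r) grid size.
#' @param reconstruct_qmax Upper Q cut for reconstruction inputs
#'   (1/Angstrom).
#' @param cylinder_init Named init vector for the elliptical-cylinder
#'   fit, or `NULL` to derive from the Guinier/P(r) stage.
#' @param reconstruct Run ab initio reconstruction per fraction.
#' @param n_runs Reconstruction runs per fraction when enabled.
#' @param seed Base seed for all stochastic stages.
#' @param resolution [resolution_spec()] used when fitting models.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(qrg_limit = 1.3,
                            dmax_candidates = seq(60, 180, by = 10),
                            n_r = 101,
                            reconstruct_qmax = 0.13,
                            cylinder_init = NULL,
                            reconstruct = FALSE,
                            n_runs = 5,
                            seed = 1,
                            resolution = resolution_spec()) {
  structure(as.list(environment()), class = "pipeline_config")
}

# run one analysis stage, capturing errors as strings
.stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) e)
  if (inherits(res, "error")) {
    report$errors[[name]] <- conditionMessage(res)
    report[[name]] <- NULL
  } else {
    report[[name]] <- res
  }
  report
}

#' Run the full per-fraction analysis
#'
#' Given a SEC-SANS run, detects elution peaks on the scattergram and
#' extracts one averaged curve per peak; given a single curve (or list
#' of curves), analyzes them directly. Each fraction then passes through
#' Guinier analysis, a Dmax scan with P(r) inversion, Kratky
#' classification, an elliptical-cylinder fit and (optionally) ab initio
#' shape reconstruction. Stage errors are captured per fraction and the
#' remaining stages continue. Deterministic given the config seed.
#'
#' @param x A `secsans_run`, a [scattering_curve()], or a list of
#'   scattering curves.
#' @param config A [pipeline_config()].
#' @return A list of `fraction_report` objects (class
#'   `pipeline_result`).
#' @export
run_pipeline <- function(x, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(x, "secsans_run")) {
    sg <- scattergram(x)
    rngs <- peak_frame_ranges(sg)
    labels <- if (length(rngs) == 2) c("high_mw", "low_mw")
              else sprintf("fraction_%d", seq_along(rngs))
    curves <- Map(function(r, lab) average_peak(x, r, label = lab),
                  rngs, labels)
    names(curves) <- labels
  } else if (inherits(x, "scattering_curve")) {
    curves <- list(custom = x)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "scattering_curve"))) {
    curves <- x
    if (is.null(names(curves)))
      names(curves) <- sprintf("fraction_%d", seq_along(curves))
  } else {
    stop("'x' must be a secsans_run, a scattering_curve, or a list of curves",
         call. = FALSE)
  }

  reports <- vector("list", length(curves))
  for (k in seq_along(curves)) {
    crv <- curves[[k]]
    rep_k <- structure(list(label = names(curves)[k], errors = list()),
                       class = "fraction_report")
    rep_k <- .stage(rep_k, "guinier",
                    fit_guinier(crv, qrg_limit = config$qrg_limit))
    rep_k <- .stage(rep_k, "dmax_scan",
                    scan_dmax(crv, config$dmax_candidates, n_r = config$n_r))
    if (!is.null(rep_k$dmax_scan)) {
      rep_k$pr <- rep_k$dmax_scan$best_pr
      rep_k$pr_moments <- tryCatch(rg_from_pr(rep_k$pr),
                                   error = function(e) NULL)
    }
    rep_k <- .stage(rep_k, "kratky", compute_kratky(crv))
    init <- config$cylinder_init
    if (is.null(init)) {
      dmax_guess <- if (!is.null(rep_k$dmax_scan)) rep_k$dmax_scan$best else 100
      i0_guess <- if (!is.null(rep_k$guinier)) rep_k$guinier$i0
                  else max(crv$intensity)
      init <- c(minor_radius = 12, axis_ratio = 2,
                length = 0.8 * dmax_guess, scale = i0_guess)
    }
    rep_k <- .stage(rep_k, "cylinder_fit",
                    fit_model(crv, "elliptical_cylinder", init,
                              resolution = config$resolution))
    if (isTRUE(config$reconstruct) && !is.null(rep_k$dmax_scan)) {
      rep_k <- .stage(rep_k, "reconstruction", {
        sub <- {
          keep <- crv$q <= config$reconstruct_qmax
          scattering_curve(crv$q[keep], crv$intensity[keep],
                           crv$sigma[keep], label = crv$label)
        }
        dmx <- rep_k$dmax_scan$best
        models <- lapply(seq_len(config$n_runs), function(j)
          reconstruct_shape(sub, dmx, symmetry = "P1",
                            config = anneal_config(
                              seed = config$seed + 1000 * k + j)))
        aligned <- align_models(models)
        avg <- average_models(aligned)
        pairs <- utils::combn(length(aligned), 2)
        nsds <- apply(pairs, 2, function(ij)
          nsd(aligned[[ij[1]]], aligned[[ij[2]]]))
        list(n_runs = config$n_runs, mean_nsd = mean(nsds),
             average_model = avg)
      })
    }
    reports[[k]] <- rep_k
  }
  structure(reports, class = "pipeline_result")
}

#' @export
print.fraction_report <- function(x, ...) {
  cat(sprintf("== Fraction: %s ==\n", x$label))
  if (!is.null(x$guinier))
    cat(sprintf("  Guinier:   Rg = %.2f A, I(0) = %.4g (%.2f < QRg < %.2f)\n",
                x$guinier$rg, x$guinier$i0, x$guinier$qrg_bounds[1],
                x$guinier$qrg_bounds[2]))
  if (!is.null(x$pr_moments))
    cat(sprintf("  P(r):      Rg = %.2f A, I(0) = %.4g, Dmax = %.0f A\n",
                x$pr_moments$rg, x$pr_moments$i0, x$pr$dmax))
  if (!is.null(x$kratky))
    cat(sprintf("  Kratky:    %s\n", x$kratky$classification))
  if (!is.null(x$cylinder_fit)) {
    p <- x$cylinder_fit$params
    cat(sprintf(
      "  Cylinder:  a = %.2f A, nu = %.2f, L = %.1f A, chi^2 = %.3g\n",
      p[["minor_radius"]], p[["axis_ratio"]], p[["length"]],
      x$cylinder_fit$reduced_chi2))
  }
  if (!is.null(x$reconstruction))
    cat(sprintf("  Ab initio: %d runs, mean pairwise NSD = %.2f\n",
                x$reconstruction$n_runs, x$reconstruction$mean_nsd))
  for (nm in names(x$errors))
    cat(sprintf("  [stage %s failed: %s]\n", nm, x$errors[[nm]]))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' Serialize a pipeline result to JSON
#'
#' A stable, numbers-only summary (no environments or model objects):
#' per fraction the Guinier, P(r), Kratky and cylinder-fit quantities,
#' plus reconstruction summaries when present. Byte-identical across
#' repeated runs with identical inputs and seeds.
#'
#' @param result A [run_pipeline()] result.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
report_json <- function(result, path = NULL) {
  stopifnot(inherits(result, "pipeline_result"))
  out <- lapply(result, function(x) {
    o <- list(label = x$label)
    if (!is.null(x$guinier))
      o$guinier <- list(rg = x$guinier$rg, i0 = x$guinier$i0,
                        qrg_bounds = x$guinier$qrg_bounds,
                        fit_quality = x$guinier$fit_quality)
    if (!is.null(x$pr))
      o$pr <- list(dmax = x$pr$dmax, alpha = x$pr$alpha,
                   fit_chi2 = x$pr$fit_chi2,
                   rg = x$pr_moments$rg %||% NA,
                   i0 = x$pr_moments$i0 %||% NA)
    if (!is.null(x$kratky)) o$kratky <- x$kratky$classification
    if (!is.null(x$cylinder_fit))
      o$cylinder_fit <- list(params = as.list(x$cylinder_fit$params),
                             reduced_chi2 = x$cylinder_fit$reduced_chi2)
    if (!is.null(x$reconstruction))
      o$reconstruction <- list(n_runs = x$reconstruction$n_runs,
                               mean_nsd = x$reconstruction$mean_nsd)
    if (length(x$errors)) o$errors <- x$errors
    o
  })
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
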