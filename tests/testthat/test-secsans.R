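test_that("reference components: geometry registry, Rg ordering,
           compactness, forward scaling", {
  expect_error(make_reference_components("bogus"), "unknown geometry")
  comps <- make_reference_components()
  rg_h <- fit_guinier(comps$high_mw$reference_curve)$rg
  rg_l <- fit_guinier(comps$low_mw$reference_curve)$rg
  expect_gt(rg_h, rg_l)
  expect_identical(
    compute_kratky(comps$high_mw$reference_curve)$classification, "folded")
  expect_identical(
    compute_kratky(comps$low_mw$reference_curve)$classification, "folded")

  scaled <- make_reference_components(i0 = c(high = 0.15, low = 0.036))
  expect_equal(scaled$high_mw$reference_curve$intensity /
                 comps$high_mw$reference_curve$intensity,
               rep(2, 90), tolerance = 1e-10)
  expect_equal(scaled$low_mw$reference_curve$intensity /
                 comps$low_mw$reference_curve$intensity,
               rep(0.5, 90), tolerance = 1e-10)
})

test_that("noise-free single-component frames are exactly the elution
           profile times the reference", {
  comps <- make_reference_components()
  run <- simulate_run(comps["low_mw"], n_frames = 40,
                      background_level = 0.001, noise_scale = 0, seed = 1)
  cc <- comps$low_mw
  prof <- exp(-(seq_len(40) - cc$peak_center)^2 / (2 * cc$peak_width^2))
  for (f in c(10, 30, 36)) {
    expect_lt(max(abs(run$frames[, f] - 0.001 -
                        prof[f] * cc$reference_curve$intensity)), 1e-12)
  }
})

test_that("the run is reproducible from its seed", {
  comps <- make_reference_components()
  r1 <- simulate_run(comps, seed = 99)
  r2 <- simulate_run(comps, seed = 99)
  expect_identical(r1$frames, r2$frames)
  r3 <- simulate_run(comps, seed = 100)
  expect_false(identical(r1$frames, r3$frames))
})

test_that("averaging many noisy realizations converges on the noise-free
           frame", {
  comps <- make_reference_components()
  f <- 18
  clean <- simulate_run(comps, noise_scale = 0, seed = 1)$frames[, f]
  reals <- vapply(1:100, function(s)
    simulate_run(comps, seed = s)$frames[, f], numeric(90))
  se <- simulate_run(comps, seed = 1)$sigma[, f] / sqrt(100)
  z <- abs(rowMeans(reals) - clean) / se
  expect_gt(mean(z < 3), 0.98)
  expect_true(all(z < 5))
})

test_that("scattergram finds the configured peaks and none for empty
           elutions", {
  comps <- make_reference_components()
  run <- simulate_run(comps, seed = 8)
  sg <- scattergram(run)
  expect_length(sg$peaks, 2)
  expect_lte(abs(sg$peaks[1] - comps$high_mw$peak_center), 1)
  expect_lte(abs(sg$peaks[2] - comps$low_mw$peak_center), 1)

  empty <- lapply(comps, function(cc) {
    cc$amplitude <- 0
    cc
  })
  sg0 <- scattergram(simulate_run(empty, seed = 8))
  expect_length(sg0$peaks, 0)
})

test_that("peak heights follow the configured amplitudes and the count is
           scale invariant", {
  ref <- make_reference_components()$low_mw$reference_curve
  comps <- list(elution_component(ref, 15, 3, amplitude = 2),
                elution_component(ref, 45, 3, amplitude = 1))
  run <- simulate_run(comps, seed = 5)
  sg <- scattergram(run)
  expect_length(sg$peaks, 2)
  expect_equal(sg$total[sg$peaks[1]] / sg$total[sg$peaks[2]], 2,
               tolerance = 0.1)

  scaled <- run
  scaled$frames <- run$frames * 250
  scaled$sigma <- run$sigma * 250
  scaled$background_level <- run$background_level * 250
  expect_identical(scattergram(scaled)$peaks, sg$peaks)
})

test_that("frame averaging pools variance like sqrt(n)", {
  ref <- make_reference_components()$low_mw$reference_curve
  comps <- list(elution_component(ref, 20, 1e6, amplitude = 1))
  run <- simulate_run(comps, n_frames = 36, noise_scale = 0.005, seed = 3)
  one <- average_peak(run, 1)
  nine <- average_peak(run, 1:9)
  expect_equal(mean(one$sigma / nine$sigma), 3, tolerance = 0.1)
})

test_that("a clean peak average recovers the generating curve within its
           pooled uncertainty", {
  comps <- make_reference_components(centers = c(high = 12, low = 48))
  run <- simulate_run(comps, seed = 21)
  sg <- scattergram(run)
  rng <- peak_frame_ranges(sg)[[2]]
  avg <- average_peak(run, rng)
  # exact oracle: the same inverse-variance weights applied to the
  # noise-free frames of an identically configured run
  clean <- simulate_run(comps, noise_scale = 0, seed = 21)
  w <- 1 / run$sigma[, rng, drop = FALSE]^2
  expected <- rowSums(w * (clean$frames[, rng, drop = FALSE] -
                             run$background_level)) / rowSums(w)
  expect_gt(mean(abs(avg$intensity - expected) < 2 * avg$sigma), 0.90)
})

test_that("the contaminating mixture weight under peak overlap equals the
           Gaussian-overlap fraction", {
  comps <- make_reference_components()
  run <- simulate_run(comps, noise_scale = 0, seed = 1)
  rng <- 16:20                                # around the high-MW peak
  avg <- average_peak(run, rng)
  r_high <- comps$high_mw$reference_curve$intensity
  r_low <- comps$low_mw$reference_curve$intensity
  fit <- stats::lm(avg$intensity ~ r_high + r_low - 1)
  w_high <- mean(exp(-(rng - comps$high_mw$peak_center)^2 /
                       (2 * comps$high_mw$peak_width^2)))
  w_low <- mean(exp(-(rng - comps$low_mw$peak_center)^2 /
                      (2 * comps$low_mw$peak_width^2)))
  expect_equal(unname(stats::coef(fit)[1]), w_high, tolerance = 0.05)
  expect_equal(unname(stats::coef(fit)[2]) / unname(stats::coef(fit)[1]),
               w_low / w_high, tolerance = 0.05)
})

test_that("end to end: peak-averaged curves recover each component's
           Guinier Rg within 3%", {
  comps <- make_reference_components()
  run <- simulate_run(comps, seed = 42)
  sg <- scattergram(run)
  rngs <- peak_frame_ranges(sg)
  refs <- list(comps$high_mw$reference_curve, comps$low_mw$reference_curve)
  for (k in 1:2) {
    rg_ref <- fit_guinier(refs[[k]])$rg
    rg_got <- fit_guinier(average_peak(run, rngs[[k]]))$rg
    expect_equal(rg_got, rg_ref, tolerance = 0.03)
  }
})

test_that("runs survive a directory write/read round trip", {
  comps <- make_reference_components()
  run <- simulate_run(comps, seed = 77)
  d <- withr::local_tempdir()
  write_run(run, d)
  back <- read_run(d)
  expect_equal(back$frames, run$frames, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$background_level, run$background_level)
  expect_identical(scattergram(back)$peaks, scattergram(run)$peaks)
})

test_that("simulate_run validates its inputs", {
  comps <- make_reference_components()
  expect_error(simulate_run(comps, n_frames = 5), "n_frames")
  expect_error(simulate_run(comps, noise_scale = -1), "noise_scale")
  expect_error(average_peak(simulate_run(comps), integer(0)), "empty")
})
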