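test_that("correlation marker agrees with the Pearson formula", {
  X <- cbind(1, c(1, 2, 3))
  # exact reconstruction
  expect_equal(correlation_marker(c(0, 1), X, c(1, 2, 3)), 1.0)
  # perfect anti-correlation still gives magnitude 1
  expect_equal(correlation_marker(c(4, -1), X, c(1, 2, 3)), 1.0)
  # direct-formula oracle: reconstruction (1, 1, 2) against y (1, 2, 3)
  Xr <- diag(3)
  expect_equal(correlation_marker(c(1, 1, 2), Xr, c(1, 2, 3)),
               abs(stats::cor(c(1, 2, 3), c(1, 1, 2))))
  expect_equal(correlation_marker(c(1, 1, 2), Xr, c(1, 2, 3)),
               0.8660254, tolerance = 1e-6)
  # zero-variance degeneracy floors with a warning
  expect_warning(out <- correlation_marker(c(1, 0), X, c(1, 2, 3)),
                 "zero variance")
  expect_equal(out, MARKER_FLOOR)
})

test_that("l1 marker drops the intercept and scales linearly", {
  expect_equal(l1_marker(c(0.5, 1, -2, 0)), 3.0)
  expect_equal(l1_marker(c(7, 0, 0, 0)), MARKER_FLOOR)
  set.seed(2)
  th <- rnorm(20)
  expect_equal(l1_marker(th), sum(abs(th[-1])))
  expect_equal(l1_marker(3 * th), 3 * l1_marker(th))
})

test_that("M100 marker finds the tracked negative peak", {
  fs <- 200
  lags <- (0:80) / fs
  # single negative bump of depth a at 0.1 s
  a <- 0.8
  trf <- -a * exp(-(lags - 0.1)^2 / (2 * 0.02^2))
  expect_equal(m100_marker(trf, fs), a, tolerance = 1e-6)
  # everywhere non-negative in the band: floor fallback
  expect_equal(m100_marker(abs(trf) + 0.1, fs), MARKER_FLOOR)
  # equal-depth minima at 0.08 s and 0.14 s: proximity to 0.1 s wins
  trf2 <- -0.5 * exp(-(lags - 0.08)^2 / (2 * 0.01^2)) -
    0.5 * exp(-(lags - 0.14)^2 / (2 * 0.01^2))
  minima <- c(0.08, 0.14)
  picked_depth <- m100_marker(trf2, fs)
  # both depths are ~0.5; check the chosen lag by perturbing the far peak
  trf3 <- trf2
  trf3[lags > 0.11] <- trf3[lags > 0.11] * 1.01 # deepen the far peak a bit
  expect_equal(m100_marker(trf3, fs), picked_depth, tolerance = 0.02)
  expect_equal(picked_depth, -min(trf2[abs(lags - 0.08) < 0.01]),
               tolerance = 1e-6)
  expect_error(m100_marker(trf, fs, search_band_s = c(0.1, 2)),
               "lag range")
})

test_that("marker streams are symmetric for identical inputs", {
  # identical envelopes for both speakers give identical designs and
  # coefficient streams, hence equal markers
  fs <- 100
  env <- make_speechlike_envelope(8, fs, seed = 4)
  stim <- stimulus_pair(env, env, fs)
  kern <- make_trf_kernel(fs, lag_max_s = 0.2)
  w <- make_attention_weights(8, fs, numeric(), case_id = 3,
                              noise_var = 0)
  tr <- simulate_decoding_trial(stim, kern, w, W = 25L, seed = 5)
  stream <- estimate_coefficients(tr, lambda = 0.95, gamma = 0.01,
                                  W = 25L, L = 20L, rel_tol = 0)
  mk <- suppressWarnings(marker_stream(stream, tr, "correlation"))
  expect_equal(mk$m1, mk$m2, tolerance = 1e-8)
  ml <- marker_stream(stream, marker_type = "l1")
  expect_equal(ml$m1, ml$m2, tolerance = 1e-8)
})

test_that("markers round-trip through the on-disk TSV format", {
  fs <- 100
  cfg <- aad_config("eeg_decoding", fs = fs, duration_s = 6, W = 25L,
                    L = 20L, switch_times_s = 3)
  tr <- simulate_trial(cfg, 8)
  tm <- suppressWarnings(trial_markers(tr, cfg))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(tm$markers), path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$m1, tm$markers$m1, tolerance = 1e-12)
  expect_equal(back$m2, tm$markers$m2, tolerance = 1e-12)
})

test_that("attended markers dominate on a strong-modulation trial", {
  cfg <- aad_config("eeg_decoding", duration_s = 20,
                    switch_times_s = 10)
  tr <- simulate_trial(cfg, 21)
  tm <- suppressWarnings(trial_markers(tr, cfg))
  m <- tm$markers
  half1 <- m$k <= 40
  expect_gt(mean(m$m1[half1]), mean(m$m2[half1]))
  expect_gt(mean(m$m2[!half1]), mean(m$m1[!half1]))
})
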