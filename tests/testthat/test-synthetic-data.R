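test_that("speech-like envelopes are positive, reproducible and slow", {
  env <- make_speechlike_envelope(60, 200, seed = 1)
  expect_length(env, 12000L)
  expect_true(all(env >= 0))
  expect_identical(env, make_speechlike_envelope(60, 200, seed = 1))
  expect_false(identical(env, make_speechlike_envelope(60, 200, seed = 2)))

  sp <- stats::spec.pgram(env - mean(env), plot = FALSE, taper = 0)
  f_hz <- sp$freq * 200
  expect_gte(sum(sp$spec[f_hz < 10]) / sum(sp$spec), 0.80)

  expect_error(make_speechlike_envelope(-1, 200), "positive")
  expect_error(make_speechlike_envelope(10, 0), "positive")
})

test_that("TRF kernel places and smooths lag components correctly", {
  # degenerate smoothing leaves the sparse train untouched
  k0 <- make_trf_kernel(200, components = list(lag_s = 0.1,
                                               amplitude = -1.0),
                        smoothing_std_s = 0)
  expect_equal(k0$values[round(0.1 * 200) + 1L], -1.0)
  expect_equal(sum(k0$values != 0), 1L)

  # unit-area smoothing conserves total mass
  k <- make_trf_kernel(200)
  expect_equal(sum(k$values), sum(default_trf_components()$amplitude),
               tolerance = 1e-6)

  # significant peaks sit at the component lags
  pos_peak <- k$lags_s[which.max(k$values)]
  neg_peak <- k$lags_s[which.min(k$values)]
  expect_equal(pos_peak, 0.05, tolerance = 0.005)
  expect_equal(neg_peak, 0.10, tolerance = 0.005)

  expect_error(make_trf_kernel(200, components = list(lag_s = -0.1,
                                                      amplitude = 1)),
               ">= 0")
})

test_that("attention weights implement the step exchange and noise level", {
  w <- make_attention_weights(60, 200, 30, case_id = 1, noise_var = 0,
                              seed = 1)
  t_s <- (seq_len(12000) - 0.5) / 200
  expect_true(all(w$w1[t_s < 30] > w$w2[t_s < 30]))
  expect_true(all(w$w1[t_s > 30] < w$w2[t_s > 30]))
  # total stimulus drive conserved
  expect_equal(w$w1 + w$w2, rep(0.5, 12000))

  # Monte-Carlo check of the injected weight-noise variance
  wn <- make_attention_weights(60, 200, 30, case_id = 1,
                               noise_var = 4e-4, seed = 7)
  v <- stats::var(wn$w1 - wn$w1_clean)
  expect_lt(abs(v - 4e-4) / 4e-4, 0.20)

  expect_error(make_attention_weights(60, 200, 30, case_id = 9),
               "case_id")
  expect_error(make_attention_weights(60, 200, 70, case_id = 1),
               "inside")
})

test_that("decoding-model generator matches its closed forms and oracle", {
  fs <- 100
  n <- 20L
  s1 <- runif(n)
  s2 <- runif(n)
  stim <- stimulus_pair(s1, s2, fs)

  # identity kernel, pure speaker-1 drive
  ident <- make_trf_kernel(fs, components = list(lag_s = 0, amplitude = 1),
                           smoothing_std_s = 0, lag_max_s = 0.05)
  w10 <- make_attention_weights(n / fs, fs, numeric(), case_id = 1,
                                noise_var = 0, levels = c(1, 0))
  tr <- simulate_decoding_trial(stim, ident, w10, mean_offset = 0,
                                noise_var = 0, W = 5L)
  expect_equal(tr$neural, s1)

  # both weights zero: response is the constant offset
  w00 <- make_attention_weights(n / fs, fs, numeric(), case_id = 1,
                                noise_var = 0, levels = c(0, 0))
  tr0 <- simulate_decoding_trial(stim, ident, w00, mean_offset = 0.02,
                                 noise_var = 0, W = 5L)
  expect_equal(tr0$neural, rep(0.02, n))

  # brute-force double-loop oracle on a small instance
  kern <- make_trf_kernel(fs, components = data.frame(
    lag_s = c(0, 0.03, 0.07), amplitude = c(0.4, -1, 0.3)),
    smoothing_std_s = 0, lag_max_s = 0.1)
  w <- make_attention_weights(n / fs, fs, 0.1, case_id = 2,
                              noise_var = 0, seed = 3)
  tr2 <- simulate_decoding_trial(stim, kern, w, mean_offset = 0.02,
                                 noise_var = 0, W = 5L)
  eref <- brute_decoding_response(s1, s2, kern$values, w$w1, w$w2,
                                  0.02, numeric(n))
  expect_equal(tr2$neural, eref, tolerance = 1e-12)

  # Eq.-4 linearity: (w1, w2) = (w1, 0) + (0, w2) up to one offset
  wa <- make_attention_weights(n / fs, fs, numeric(), case_id = 1,
                               noise_var = 0, levels = c(0.4, 0))
  wb <- make_attention_weights(n / fs, fs, numeric(), case_id = 1,
                               noise_var = 0, levels = c(0, 0.1))
  wab <- make_attention_weights(n / fs, fs, numeric(), case_id = 1,
                                noise_var = 0, levels = c(0.4, 0.1))
  # levels = (att, unatt); with no switches speaker 1 holds the first level
  ea <- simulate_decoding_trial(stim, kern, wa, 0.02, 0, W = 5L)$neural
  eb <- simulate_decoding_trial(stim, kern, wb, 0.02, 0, W = 5L)$neural
  eab <- simulate_decoding_trial(stim, kern, wab, 0.02, 0, W = 5L)$neural
  expect_equal(ea + eb - 0.02, eab, tolerance = 1e-12)

  # reproducibility with noise
  ta <- simulate_decoding_trial(stim, kern, w, seed = 11, W = 5L)
  tb <- simulate_decoding_trial(stim, kern, w, seed = 11, W = 5L)
  expect_identical(ta$neural, tb$neural)
})

test_that("encoding-model generator follows the truth schedule", {
  fs <- 100
  n <- 20L
  s1 <- runif(n)
  s2 <- runif(n)
  stim <- stimulus_pair(s1, s2, fs)
  ka <- make_trf_kernel(fs, components = data.frame(
    lag_s = c(0.02, 0.05), amplitude = c(0.5, -1)),
    smoothing_std_s = 0, lag_max_s = 0.1)
  ku <- make_trf_kernel(fs, components = data.frame(
    lag_s = c(0.02, 0.05), amplitude = c(0.5, -0.3)),
    smoothing_std_s = 0, lag_max_s = 0.1)
  sched <- rep(c(1L, 2L), each = n / 2)

  # identical kernels: schedule is irrelevant
  t1 <- simulate_encoding_trial(stim, ka, ka, sched, noise_var = 0, W = 5L)
  t2 <- simulate_encoding_trial(stim, ka, ka, rev(sched), noise_var = 0,
                                W = 5L)
  expect_equal(t1$neural, t2$neural)

  # zero unattended kernel: response is the attended convolution alone
  k0 <- make_trf_kernel(fs, components = data.frame(lag_s = 0,
                                                    amplitude = 0),
                        smoothing_std_s = 0, lag_max_s = 0.1)
  t3 <- simulate_encoding_trial(stim, ka, k0, rep(1L, n), noise_var = 0,
                                W = 5L)
  expect_equal(t3$neural, causal_convolve(s1, ka$values))

  # brute-force oracle with a mid-trial switch
  t4 <- simulate_encoding_trial(stim, ka, ku, sched, noise_var = 0,
                                W = 5L)
  c1a <- causal_convolve(s1, ka$values)
  c1u <- causal_convolve(s1, ku$values)
  c2a <- causal_convolve(s2, ka$values)
  c2u <- causal_convolve(s2, ku$values)
  eref <- ifelse(sched == 1L, c1a + c2u, c2a + c1u)
  expect_equal(t4$neural, eref)
})

test_that("truth labels are the window majority of the noiseless weights", {
  fs <- 100
  # switch mid-window so the majority rule is exercised
  w <- make_attention_weights(1, fs, 0.52, case_id = 1, noise_var = 0)
  stim <- stimulus_pair(runif(100), runif(100), fs)
  kern <- make_trf_kernel(fs, components = list(lag_s = 0, amplitude = 1),
                          smoothing_std_s = 0, lag_max_s = 0.05)
  tr <- simulate_decoding_trial(stim, kern, w, W = 25L)
  # windows end at 0.25/0.5/0.75/1.0 s; the third window is mostly
  # speaker 2 (switch at 0.52 s)
  expect_equal(tr$truth$attended, c(1L, 1L, 2L, 2L))
})

test_that("trial directories round-trip through write/read", {
  dir <- withr::local_tempdir()
  cfg <- aad_config("eeg_decoding", duration_s = 5, switch_times_s = 2.5)
  tr <- simulate_trial(cfg, 3)
  write_trial(tr, dir)
  expect_true(all(file.exists(file.path(
    dir, c("stimuli.tsv", "neural.tsv", "truth.tsv", "meta.json")))))
  rt <- read_trial(dir)
  expect_equal(rt$neural, tr$neural, tolerance = 1e-10)
  expect_equal(rt$truth$attended, tr$truth$attended)
  expect_equal(rt$fs, tr$fs)
})
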