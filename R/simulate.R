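#' Causal convolution with zero pre-history
#'
#' `y_t = sum_{l=0}^{L} h_l x_{t-l}` with `x_t = 0` for `t <= 0`, matching
#' streaming operation where no samples exist before the trial starts.
#'
#' @param x Numeric signal.
#' @param h Numeric impulse response (`h[1]` is the lag-0 tap).
#' @return Numeric vector of `length(x)`.
#' @export
causal_convolve <- function(x, h) {
  n <- length(x)
  L <- length(h) - 1L
  y <- stats::filter(c(numeric(L), x), h, method = "convolution", sides = 1)
  as.numeric(y[(L + 1L):(L + n)])
}

.window_truth <- function(attended_sample, fs, W) {
  K <- floor(length(attended_sample) / W)
  k <- seq_len(K)
  att <- vapply(k, function(kk) {
    seg <- attended_sample[((kk - 1L) * W + 1L):(kk * W)]
    # majority attended sample within the window; ties go to speaker 1
    if (mean(seg == 1L) >= 0.5) 1L else 2L
  }, integer(1))
  tibble::tibble(k = k, t_start_s = (k - 1L) * W / fs, attended = att)
}

#' Simulate a dual-speaker decoding-model trial
#'
#' Generates a single synthetic neural response channel from the forward
#' convolutional model
#' `e_t = w_t^(1) (s^(1) * h)_t + w_t^(2) (s^(2) * h)_t + mu + u_t`,
#' where `h` is a shared TRF kernel, the weights carry the attentional
#' modulation, `mu` is a constant offset and `u_t` is i.i.d. Gaussian noise.
#' Ground-truth per-instance labels are derived from the noiseless weights
#' (majority attended sample within each window of `W` samples).
#'
#' @param stimuli An [stimulus_pair()].
#' @param kernel An [make_trf_kernel()] result on the same sampling rate.
#' @param weights An [make_attention_weights()] result of matching length.
#' @param mean_offset Constant offset `mu` (default 0.02).
#' @param noise_var Variance of the additive response noise (default 2.5e-5).
#' @param seed Integer seed for the response noise.
#' @param W Window length in samples used to derive per-instance truth
#'   labels (default 50).
#'
#' @return Object of class `aad_sim_trial`: list with `stimuli`, `neural`
#'   (numeric vector `e_t`), `weights`, `truth` (tibble `k`, `t_start_s`,
#'   `attended`), `attended_sample`, `mode = "decoding"`, `fs`, `W`,
#'   `mean_offset`, `noise_var`, `seed`.
#' @export
simulate_decoding_trial <- function(stimuli, kernel, weights,
                                    mean_offset = 0.02, noise_var = 2.5e-5,
                                    seed = 1L, W = 50L) {
  n <- length(stimuli$envelope1)
  if (length(weights$w1) != n) {
    stop("weights and envelopes have mismatched lengths", call. = FALSE)
  }
  if (!isTRUE(all.equal(stimuli$fs, kernel$fs))) {
    stop("stimuli and kernel sampling rates differ", call. = FALSE)
  }
  c1 <- causal_convolve(stimuli$envelope1, kernel$values)
  c2 <- causal_convolve(stimuli$envelope2, kernel$values)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  u <- stats::rnorm(n, sd = sqrt(noise_var))
  e <- weights$w1 * c1 + weights$w2 * c2 + mean_offset + u
  structure(
    list(stimuli = stimuli, neural = e, weights = weights,
         truth = .window_truth(weights$attended, stimuli$fs, W),
         attended_sample = weights$attended, mode = "decoding",
         fs = stimuli$fs, W = as.integer(W), mean_offset = mean_offset,
         noise_var = noise_var, seed = as.integer(seed)),
    class = "aad_sim_trial"
  )
}

#' Simulate a dual-speaker encoding-model trial
#'
#' Generates an auditory-component response with attention-modulated TRFs:
#' `E_t = (s^(a) * h_att)_t + (s^(u) * h_unatt)_t + u_t`, where at every
#' sample the attended speaker `a` follows `truth_schedule` and the attended
#' kernel carries the larger-magnitude negative (M100-like) component near
#' the 0.1 s lag.
#'
#' @param stimuli An [stimulus_pair()].
#' @param kernel_attended,kernel_unattended TRF kernels on the same lag grid.
#' @param truth_schedule Integer vector (1 or 2) of per-sample attended
#'   speaker, same length as the envelopes.
#' @param noise_var Variance of the additive response noise.
#' @param seed Integer seed.
#' @param W Window length in samples for per-instance truth labels.
#'
#' @return Object of class `aad_sim_trial` with `mode = "encoding"`.
#' @export
simulate_encoding_trial <- function(stimuli, kernel_attended,
                                    kernel_unattended, truth_schedule,
                                    noise_var = 2.5e-5, seed = 1L, W = 50L) {
  n <- length(stimuli$envelope1)
  if (length(truth_schedule) != n) {
    stop("truth_schedule and envelopes have mismatched lengths",
         call. = FALSE)
  }
  if (length(kernel_attended$values) != length(kernel_unattended$values)) {
    stop("the two kernels must share the lag grid", call. = FALSE)
  }
  c1a <- causal_convolve(stimuli$envelope1, kernel_attended$values)
  c1u <- causal_convolve(stimuli$envelope1, kernel_unattended$values)
  c2a <- causal_convolve(stimuli$envelope2, kernel_attended$values)
  c2u <- causal_convolve(stimuli$envelope2, kernel_unattended$values)
  att1 <- truth_schedule == 1L
  E <- ifelse(att1, c1a + c2u, c2a + c1u)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  E <- E + stats::rnorm(n, sd = sqrt(noise_var))
  structure(
    list(stimuli = stimuli, neural = as.numeric(E),
         weights = NULL,
         truth = .window_truth(as.integer(truth_schedule), stimuli$fs, W),
         attended_sample = as.integer(truth_schedule), mode = "encoding",
         fs = stimuli$fs, W = as.integer(W), mean_offset = 0,
         noise_var = noise_var, seed = as.integer(seed)),
    class = "aad_sim_trial"
  )
}

#' Default unattended TRF components
#'
#' Same lag structure as [default_trf_components()] but with a shallower
#' M100-like negative deflection, so attention modulates the 0.1 s peak.
#' @return Data frame of `(lag_s, amplitude)` pairs.
#' @export
default_unattended_trf_components <- function() {
  data.frame(
    lag_s = c(0.05, 0.10, 0.15, 0.20),
    amplitude = c(0.5, -0.35, 0.2, -0.2)
  )
}

#' Write a simulated trial to a directory
#'
#' Writes `stimuli.tsv` (t_s, env1, env2), `neural.tsv` (t_s, value),
#' `truth.tsv` (k, t_start_s, attended) and `meta.json` (parameters + seed).
#'
#' @param trial An `aad_sim_trial`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(trial$neural)
  t_s <- seq_len(n) / trial$fs
  readr::write_tsv(
    tibble::tibble(t_s = t_s, env1 = trial$stimuli$envelope1,
                   env2 = trial$stimuli$envelope2),
    file.path(dir, "stimuli.tsv")
  )
  readr::write_tsv(tibble::tibble(t_s = t_s, value = trial$neural),
                   file.path(dir, "neural.tsv"))
  readr::write_tsv(trial$truth, file.path(dir, "truth.tsv"))
  meta <- list(mode = trial$mode, fs = trial$fs, W = trial$W,
               mean_offset = trial$mean_offset, noise_var = trial$noise_var,
               seed = trial$seed, duration_s = n / trial$fs)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a simulated trial directory
#'
#' Counterpart of [write_trial()].
#'
#' @param dir Directory containing `stimuli.tsv`, `neural.tsv`, `truth.tsv`
#'   and `meta.json`.
#' @return An `aad_sim_trial` (without the weight sequences, which are not
#'   serialised).
#' @export
read_trial <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  st <- readr::read_tsv(file.path(dir, "stimuli.tsv"),
                        show_col_types = FALSE)
  ne <- readr::read_tsv(file.path(dir, "neural.tsv"), show_col_types = FALSE)
  tr <- readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  structure(
    list(stimuli = stimulus_pair(st$env1, st$env2, meta$fs),
         neural = ne$value, weights = NULL,
         truth = tibble::as_tibble(tr), attended_sample = NULL,
         mode = meta$mode, fs = meta$fs, W = as.integer(meta$W),
         mean_offset = meta$mean_offset, noise_var = meta$noise_var,
         seed = as.integer(meta$seed)),
    class = "aad_sim_trial"
  )
}
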