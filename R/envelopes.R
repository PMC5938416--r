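#' Generate a speech-like amplitude envelope
#'
#' Synthesises a non-negative, temporally correlated envelope whose
#' modulation energy is concentrated in the slow (roughly 1-8 Hz) band that
#' carries the syllabic rhythm of natural speech. The construction is
#' rectified low-pass-filtered Gaussian noise plus a small positive floor:
#' white noise is passed through a 4th-order Butterworth low-pass filter with
#' an 8 Hz cutoff (applied forward-backward for zero phase), negative
#' excursions are clipped, and a floor is added so the envelope is strictly
#' positive, as a log-scale speech envelope would be.
#'
#' @param duration_s Trial length in seconds (> 0).
#' @param fs Sampling rate in Hz (> 0).
#' @param seed Integer seed; the output is deterministic given the seed.
#' @param cutoff_hz Low-pass cutoff of the modulation content in Hz.
#' @param floor Positive floor added after rectification.
#'
#' @return Numeric vector of length `round(duration_s * fs)`, all values
#'   strictly positive.
#' @export
make_speechlike_envelope <- function(duration_s, fs, seed = 1L,
                                     cutoff_hz = 8, floor = 0.05) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop("`fs` must be a positive number", call. = FALSE)
  }
  n <- round(duration_s * fs)
  # pad so the zero-phase filter transient does not touch the kept segment
  pad <- ceiling(fs)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  w <- stats::rnorm(n + 2L * pad)
  bf <- signal::butter(4, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  sm <- signal::filtfilt(bf, w)
  sm <- sm[(pad + 1L):(pad + n)]
  # normalise modulation depth, rectify, add floor
  sm <- sm / stats::sd(sm) * 0.15
  env <- pmax(sm, 0) + floor
  env
}

# Save/restore global RNG state so generators are self-seeding without
# clobbering the caller's stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Construct a temporal response function (TRF) kernel
#'
#' Places a sparse train of lag components on the `1/fs` grid and smooths it
#' with a unit-area Gaussian kernel, emulating the canonical auditory TRF
#' with an M50-like positive deflection near 50 ms and an M100-like negative
#' deflection near 100 ms, plus smaller later components.
#'
#' @param fs Sampling rate in Hz.
#' @param components List (or data frame) of `(lag_s, amplitude)` pairs; all
#'   lags must be >= 0. Defaults to +0.5 at 50 ms, -1.0 at 100 ms, +0.2 at
#'   150 ms and -0.2 at 200 ms.
#' @param smoothing_std_s Standard deviation of the Gaussian smoother in
#'   seconds (default 0.010 s). `0` leaves the sparse train unsmoothed.
#' @param lag_max_s Extent of the lag grid in seconds.
#'
#' @return An object of class `aad_trf_kernel`: a list with `lags_s`,
#'   `values`, `fs` and `smoothing_std_s`. The smoothing conserves the sum of
#'   the component amplitudes.
#' @export
make_trf_kernel <- function(fs,
                            components = default_trf_components(),
                            smoothing_std_s = 0.010,
                            lag_max_s = 0.4) {
  comp <- as.data.frame(components)
  names(comp) <- c("lag_s", "amplitude")[seq_len(ncol(comp))]
  if (any(comp$lag_s < 0)) stop("component lags must be >= 0", call. = FALSE)
  n_lag <- round(lag_max_s * fs) + 1L
  lags_s <- (seq_len(n_lag) - 1L) / fs
  h <- numeric(n_lag)
  idx <- round(comp$lag_s * fs) + 1L
  for (i in seq_along(idx)) h[idx[i]] <- h[idx[i]] + comp$amplitude[i]
  if (smoothing_std_s > 0) {
    half <- ceiling(4 * smoothing_std_s * fs)
    g <- stats::dnorm(seq(-half, half), sd = smoothing_std_s * fs)
    g <- g / sum(g) # unit area on the sample grid
    full <- c(numeric(half), h, numeric(half))
    sm <- stats::convolve(full, rev(g), type = "open")
    # align: convolution of padded signal with centred kernel
    h <- sm[(2L * half + 1L):(2L * half + n_lag)]
  }
  structure(
    list(lags_s = lags_s, values = h, fs = fs,
         smoothing_std_s = smoothing_std_s),
    class = "aad_trf_kernel"
  )
}

#' Default TRF lag components
#'
#' @return Data frame of `(lag_s, amplitude)` pairs.
#' @export
default_trf_components <- function() {
  data.frame(
    lag_s = c(0.05, 0.10, 0.15, 0.20),
    amplitude = c(0.5, -1.0, 0.2, -0.2)
  )
}

#' Attention-modulated mixing weights
#'
#' Builds the pair of per-sample weight sequences that set the contribution
#' of each speaker to the simulated neural response. The noiseless weights
#' are piecewise constant, exchanging values at each switch time so that
#' exactly one speaker carries the larger ("attended") weight at every
#' sample; i.i.d. Gaussian noise of variance `noise_var` models background
#' neural processes that blur the contributions. Three separation levels are
#' provided: case 1 (0.40 vs 0.10), case 2 (0.30 vs 0.20) and case 3
#' (0.26 vs 0.24); the attended + unattended total is 0.5 in every case so
#' the overall stimulus drive is conserved.
#'
#' @param duration_s Trial length in seconds.
#' @param fs Sampling rate in Hz.
#' @param switch_times_s Numeric vector of switch times, strictly inside
#'   `(0, duration_s)`. Speaker 1 is attended before the first switch.
#' @param case_id Separation level, 1, 2 or 3.
#' @param noise_var Variance of the additive Gaussian weight noise
#'   (default 4e-4).
#' @param seed Integer seed for the weight noise.
#' @param levels Optional length-2 numeric `(attended, unattended)` override
#'   of the case amplitudes.
#'
#' @return An object of class `aad_attention_weights`: list with `w1`, `w2`
#'   (noisy weights), `w1_clean`, `w2_clean`, `switch_times_s`, `noise_var`,
#'   `case_id`, `fs`.
#' @export
make_attention_weights <- function(duration_s, fs, switch_times_s = numeric(),
                                   case_id = 1L, noise_var = 4e-4, seed = 1L,
                                   levels = NULL) {
  if (is.null(levels)) {
    levels <- switch(as.character(case_id),
      "1" = c(0.40, 0.10),
      "2" = c(0.30, 0.20),
      "3" = c(0.26, 0.24),
      stop("unknown `case_id`: must be 1, 2 or 3", call. = FALSE)
    )
  }
  if (any(switch_times_s <= 0) || any(switch_times_s >= duration_s)) {
    stop("switch times must lie strictly inside (0, duration_s)",
         call. = FALSE)
  }
  n <- round(duration_s * fs)
  t_s <- (seq_len(n) - 0.5) / fs
  # attended speaker flips at each switch time; speaker 1 attended first
  n_flips <- vapply(t_s, function(t) sum(switch_times_s <= t), integer(1))
  attended <- ifelse(n_flips %% 2L == 0L, 1L, 2L)
  w1_clean <- ifelse(attended == 1L, levels[1], levels[2])
  w2_clean <- ifelse(attended == 1L, levels[2], levels[1])
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  sdn <- sqrt(noise_var)
  w1 <- w1_clean + stats::rnorm(n, sd = sdn)
  w2 <- w2_clean + stats::rnorm(n, sd = sdn)
  structure(
    list(w1 = w1, w2 = w2, w1_clean = w1_clean, w2_clean = w2_clean,
         attended = attended, switch_times_s = switch_times_s,
         noise_var = noise_var, case_id = case_id, fs = fs),
    class = "aad_attention_weights"
  )
}

#' Dual-speaker stimulus pair
#'
#' Convenience constructor bundling two envelopes with their sampling rate.
#'
#' @param envelope1,envelope2 Non-negative numeric envelopes of equal length.
#' @param fs Sampling rate in Hz.
#' @return Object of class `aad_stimulus_pair`.
#' @export
stimulus_pair <- function(envelope1, envelope2, fs) {
  if (length(envelope1) != length(envelope2)) {
    stop("the two envelopes must have identical length", call. = FALSE)
  }
  if (!all(is.finite(envelope1)) || !all(is.finite(envelope2))) {
    stop("envelopes must be finite", call. = FALSE)
  }
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  structure(
    list(envelope1 = envelope1, envelope2 = envelope2, fs = fs,
         duration_s = length(envelope1) / fs),
    class = "aad_stimulus_pair"
  )
}
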