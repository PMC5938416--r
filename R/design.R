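#' Error class signalled when a streaming window is not yet complete
#' @keywords internal
window_incomplete <- function(k, needed, available) {
  rlang::abort(
    sprintf("window %d not yet complete: needs samples up to %d, have %d",
            k, needed, available),
    class = "aad_window_incomplete"
  )
}

#' Build the decoding-model design for one window
#'
#' For window `k` (samples `(k-1)W+1 .. kW`), row `t - (k-1)W` of the
#' covariate matrix is `[1, e_t', e_{t+1}', ..., e_{t+L_d}']` over the `C`
#' response channels, and the response vector is the requested speaker's
#' envelope over the window. The decoding design looks `L_d` samples into the
#' future of each stimulus sample, so the window is only complete once sample
#' `kW + L_d` is available; otherwise a condition of class
#' `aad_window_incomplete` is signalled (streaming contract).
#'
#' @param neural Numeric vector (single channel) or `T x C` matrix of neural
#'   responses.
#' @param envelope Numeric stimulus envelope (the response variable source).
#' @param k Window index (1-based).
#' @param W Window length in samples.
#' @param L_d Decoding lag (number of future samples per channel).
#'
#' @return List with `X` (`W x (1 + C(L_d+1))`), `y` (length `W`), `k`,
#'   `mode = "decoding"`.
#' @export
build_decoding_design <- function(neural, envelope, k, W, L_d) {
  e <- if (is.matrix(neural)) neural else matrix(neural, ncol = 1L)
  C <- ncol(e)
  n_avail <- nrow(e)
  t0 <- (k - 1L) * W
  needed <- k * W + L_d
  if (needed > n_avail) window_incomplete(k, needed, n_avail)
  if (t0 + W > length(envelope)) {
    window_incomplete(k, t0 + W, length(envelope))
  }
  rows <- t0 + seq_len(W)
  X <- matrix(0, nrow = W, ncol = 1L + C * (L_d + 1L))
  X[, 1L] <- 1
  for (l in 0L:L_d) {
    X[, 1L + l * C + seq_len(C)] <- e[rows + l, , drop = FALSE]
  }
  list(X = X, y = envelope[rows], k = k, mode = "decoding")
}

#' Build the encoding-model design for one window
#'
#' For window `k`, the response is the auditory component
#' `y = [E_{(k-1)W+1}, ..., E_{kW}]` and the covariates stack an intercept
#' column with the two speakers' lagged-envelope blocks
#' `[s_t, s_{t-1}, ..., s_{t-L_e}]`. Envelope samples at `t <= 0` are taken
#' as zero (streaming causality).
#'
#' @param stimuli An [stimulus_pair()].
#' @param E Numeric auditory-component response series.
#' @param k Window index (1-based).
#' @param W Window length in samples.
#' @param L_e Encoding lag (number of past samples per speaker).
#'
#' @return List with `X` (`W x (1 + 2(L_e+1))`), `y`, `k`,
#'   `mode = "encoding"`.
#' @export
build_encoding_design <- function(stimuli, E, k, W, L_e) {
  t0 <- (k - 1L) * W
  if (k * W > length(E)) window_incomplete(k, k * W, length(E))
  rows <- t0 + seq_len(W)
  lag_block <- function(s) {
    B <- matrix(0, nrow = W, ncol = L_e + 1L)
    for (l in 0L:L_e) {
      idx <- rows - l
      ok <- idx >= 1L
      B[ok, l + 1L] <- s[idx[ok]]
    }
    B
  }
  X <- cbind(1, lag_block(stimuli$envelope1), lag_block(stimuli$envelope2))
  list(X = X, y = E[rows], k = k, mode = "encoding")
}
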