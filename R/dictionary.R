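#' Gaussian smoothing dictionary for TRF estimation
#'
#' Builds the basis matrix whose columns are peak-normalised Gaussian
#' kernels (standard deviation `kernel_std_s`, default 20 ms, the average
#' FWHM-matched width of auditory M50/M100 deflections) with means covering
#' the 0 to `lag_max_s` lag range in `spacing_s` increments, sampled on the
#' `1/fs` lag grid. The assembled dual-speaker encoding dictionary is the
#' block-diagonal `G = diag(1, G0, G0)`, which leaves the intercept
#' coordinate untouched.
#'
#' @param fs Sampling rate in Hz; `fs * lag_max_s` must be integral.
#' @param lag_max_s Lag range in seconds (default 0.4).
#' @param kernel_std_s Gaussian standard deviation in seconds (default
#'   0.020).
#' @param spacing_s Mean spacing in seconds (default 0.005); with the
#'   defaults `G0` has 81 columns.
#'
#' @return Object of class `aad_dictionary`: list with `G0`
#'   (`(L+1) x n_means`), `G` (`(1+2(L+1)) x (1+2 n_means)`), `lags_s`,
#'   `means_s`, `fs`.
#' @export
make_gaussian_dictionary <- function(fs, lag_max_s = 0.4,
                                     kernel_std_s = 0.020,
                                     spacing_s = 0.005) {
  if (spacing_s <= 0) stop("`spacing_s` must be positive", call. = FALSE)
  if (spacing_s > lag_max_s) {
    stop("`spacing_s` exceeds the lag range", call. = FALSE)
  }
  L <- round(fs * lag_max_s)
  if (abs(L - fs * lag_max_s) > 1e-8) {
    stop("`fs * lag_max_s` must be integral", call. = FALSE)
  }
  lags_s <- (0:L) / fs
  means_s <- seq(0, lag_max_s, by = spacing_s)
  G0 <- vapply(means_s, function(m) {
    col <- stats::dnorm(lags_s, mean = m, sd = max(kernel_std_s, 1e-12))
    col / max(col) # peak-normalised
  }, numeric(L + 1L))
  q <- ncol(G0)
  G <- matrix(0, nrow = 1L + 2L * (L + 1L), ncol = 1L + 2L * q)
  G[1L, 1L] <- 1
  G[1L + seq_len(L + 1L), 1L + seq_len(q)] <- G0
  G[1L + L + 1L + seq_len(L + 1L), 1L + q + seq_len(q)] <- G0
  structure(
    list(G0 = G0, G = G, lags_s = lags_s, means_s = means_s, fs = fs),
    class = "aad_dictionary"
  )
}
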