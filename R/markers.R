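#' Positivity floor applied to attention markers
#'
#' The Log-Normal observation model requires strictly positive markers;
#' correlation and l1 values can degenerate to zero.
#' @export
MARKER_FLOOR <- 1e-6

#' Correlation attention marker
#'
#' Magnitude of the Pearson correlation between a speech envelope and its
#' reconstruction by the corresponding decoder, `|corr(y, X theta)|`.
#' Returns the positivity floor (with a warning) when either series has
#' zero variance.
#'
#' @param theta Decoder coefficient vector (solve coordinates).
#' @param X Window covariate matrix.
#' @param y Window envelope vector.
#' @return Scalar in `[MARKER_FLOOR, 1]`.
#' @export
correlation_marker <- function(theta, X, y) {
  yhat <- drop(X %*% theta)
  if (length(y) < 2) stop("window too short for correlation", call. = FALSE)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warning("zero variance in correlation marker; returning floor",
            call. = FALSE)
    return(MARKER_FLOOR)
  }
  max(abs(stats::cor(y, yhat)), MARKER_FLOOR)
}

#' l1-norm attention marker
#'
#' Sum of absolute coefficient values over all non-intercept coordinates.
#' Captures the significant lag components of the decoder: an attended
#' decoder concentrates energy at informative latencies while an unattended
#' one stays small and diffuse.
#'
#' @param theta Coefficient vector whose first element is the intercept.
#' @param intercept_index Position of the intercept (default 1).
#' @return Positive scalar (floored at `MARKER_FLOOR`).
#' @export
l1_marker <- function(theta, intercept_index = 1L) {
  max(sum(abs(theta[-intercept_index])), MARKER_FLOOR)
}

#' M100-peak attention marker
#'
#' Magnitude of the negative TRF deflection near the 0.1 s lag. Local
#' minima of the lag-domain TRF inside the search band are enumerated; the
#' most negative one is returned (in magnitude), with ties in normalised
#' depth (within `tie_tol`) broken by proximity to 0.100 s. If no negative
#' local minimum exists in the band, the fallback is `max(-min(trf), floor)`
#' over the band.
#'
#' @param trf Lag-domain TRF values (intercept excluded), one speaker.
#' @param fs Sampling rate in Hz (lag grid is `0, 1/fs, ...`).
#' @param search_band_s Search band in seconds (default `c(0.06, 0.16)`).
#' @param tie_tol Tie tolerance in normalised depth (default 0.02).
#' @return Positive scalar marker.
#' @export
m100_marker <- function(trf, fs, search_band_s = c(0.06, 0.16),
                        tie_tol = 0.02) {
  lags <- (seq_along(trf) - 1L) / fs
  if (search_band_s[1] < 0 || search_band_s[2] > max(lags)) {
    stop("search band outside the available lag range", call. = FALSE)
  }
  in_band <- which(lags >= search_band_s[1] & lags <= search_band_s[2])
  # local minima over the whole grid, then restricted to the band
  n <- length(trf)
  is_min <- c(FALSE, trf[2:(n - 1)] <= trf[1:(n - 2)] &
                trf[2:(n - 1)] <= trf[3:n], FALSE)
  cand <- intersect(which(is_min & trf < 0), in_band)
  if (length(cand) > 0) {
    depth <- -trf[cand]
    rel <- depth / max(depth)
    near <- cand[rel >= 1 - tie_tol] # near-deepest set
    pick <- near[which.min(abs(lags[near] - 0.100))]
    return(max(-trf[pick], MARKER_FLOOR))
  }
  max(-min(trf[in_band]), MARKER_FLOOR)
}

#' Compute the attention-marker series for an estimated coefficient stream
#'
#' Applies the chosen marker per window and speaker, producing the positive
#' pair sequences passed to the state-space smoother. The correlation
#' marker rebuilds each window's design from the trial; the l1 and M100
#' markers operate on the stored coefficients (the M100 marker on the
#' smooth lag-domain TRF, i.e. the dictionary-mapped coefficients when a
#' dictionary was used).
#'
#' @param stream An `aad_coef_stream` from [estimate_coefficients()].
#' @param trial The trial the stream was estimated from (needed for the
#'   correlation marker).
#' @param marker_type `"correlation"`, `"l1"` or `"m100"`.
#' @param search_band_s M100 search band (seconds).
#'
#' @return Object of class `aad_markers`: tibble with columns `k`, `t_s`,
#'   `m1`, `m2` and attributes `marker_type`, `fs`, `W`.
#' @export
marker_stream <- function(stream, trial = NULL,
                          marker_type = c("correlation", "l1", "m100"),
                          search_band_s = c(0.06, 0.16)) {
  marker_type <- match.arg(marker_type)
  K <- stream$K
  fs <- stream$fs
  W <- stream$W
  m <- matrix(NA_real_, K, 2L)
  if (marker_type == "correlation") {
    if (is.null(trial)) {
      stop("the correlation marker needs the `trial`", call. = FALSE)
    }
    neural_pad <- c(trial$neural, numeric(stream$L))
    for (k in seq_len(K)) {
      d <- build_decoding_design(neural_pad, trial$stimuli$envelope1,
                                 k, W, stream$L)
      X <- if (is.null(stream$dictionary)) d$X else
        d$X %*% stream$dictionary$G
      y2 <- trial$stimuli$envelope2[((k - 1L) * W + 1L):(k * W)]
      m[k, 1L] <- correlation_marker(stream$theta[[1L]][, k], X, d$y)
      m[k, 2L] <- correlation_marker(stream$theta[[2L]][, k], X, y2)
    }
  } else if (marker_type == "l1") {
    for (k in seq_len(K)) {
      m[k, 1L] <- l1_marker(stream$effective[[1L]][, k])
      m[k, 2L] <- l1_marker(stream$effective[[2L]][, k])
    }
  } else {
    for (k in seq_len(K)) {
      m[k, 1L] <- m100_marker(effective_coefficients(stream, 1L, k), fs,
                              search_band_s)
      m[k, 2L] <- m100_marker(effective_coefficients(stream, 2L, k), fs,
                              search_band_s)
    }
  }
  out <- tibble::tibble(k = seq_len(K), t_s = seq_len(K) * W / fs,
                        m1 = pmax(m[, 1L], MARKER_FLOOR),
                        m2 = pmax(m[, 2L], MARKER_FLOOR))
  new_markers(out, marker_type, fs, W)
}

#' Construct an `aad_markers` object from a tibble
#'
#' @param data Tibble with columns `k`, `t_s`, `m1`, `m2`.
#' @param marker_type Marker label.
#' @param fs Sampling rate in Hz.
#' @param W Window length in samples.
#' @return `aad_markers` tibble.
#' @export
new_markers <- function(data, marker_type, fs, W) {
  structure(
    tibble::as_tibble(data),
    marker_type = marker_type, fs = fs, W = as.integer(W),
    class = c("aad_markers", class(tibble::tibble()))
  )
}
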