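#' Streaming estimation of encoding/decoding coefficients
#'
#' Runs the adaptive sparse filter over a trial: for each completed window
#' `k` the (optionally dictionary-transformed) design is absorbed into the
#' exponentially-weighted sufficient statistics and the l1-regularised
#' least-squares problem is re-solved by forward-backward splitting, warm
#' started at the previous window's solution. In decoding mode the problem
#' is solved separately per speech envelope, giving two independent
#' coefficient streams that share the covariate matrix; in encoding mode a
#' single problem couples both speakers' lagged envelopes.
#'
#' At the end of a trial the last decoding windows would be incomplete
#' (their covariates look `L_d` samples into the future); the neural series
#' is zero-padded past the trial end so that all `K = floor(T/W)` windows
#' yield coefficients, mirroring the zero pre-history convention.
#'
#' @param trial An `aad_sim_trial` (or a list with `stimuli`, `neural`,
#'   `fs`).
#' @param mode `"decoding"` or `"encoding"` (default `trial$mode`).
#' @param lambda Forgetting factor in `(0, 1]`.
#' @param gamma l1 penalty weight.
#' @param W Window length in samples.
#' @param L Model lag in samples (`L_d` for decoding, `L_e` for encoding).
#' @param dictionary Optional [make_gaussian_dictionary()] result; when
#'   supplied, the design is right-multiplied by `G` and the effective
#'   lag-domain coefficients are `G theta`.
#' @param tol,rel_tol,max_iter Solver settings, see [fbs_solve()].
#' @param K Number of windows to process (default `floor(T/W)`).
#'
#' @return Object of class `aad_coef_stream`: list with `theta` (list per
#'   speaker of `p x K` matrices in solve coordinates), `effective` (list
#'   per speaker of lag-domain coefficient matrices, `(L+2) x K` rows =
#'   intercept + lags), `solver_log` (tibble), `mode`, `fs`, `W`, `L`,
#'   `lambda`, `gamma`, `dictionary`.
#' @export
estimate_coefficients <- function(trial, mode = trial$mode,
                                  lambda = 0.95, gamma = 0.001,
                                  W = trial$W, L = 80L,
                                  dictionary = NULL,
                                  tol = 1e-8, rel_tol = 0.01,
                                  max_iter = 500L, K = NULL) {
  mode <- match.arg(mode, c("decoding", "encoding"))
  fs <- trial$fs
  n <- length(trial$neural)
  if (is.null(K)) K <- floor(n / W)
  G <- if (!is.null(dictionary)) dictionary$G else NULL

  if (mode == "decoding") {
    neural_pad <- c(trial$neural, numeric(L)) # complete the final windows
    p_raw <- 1L + (L + 1L)
    p <- if (is.null(G)) p_raw else ncol(G)
    stats1 <- new_sufficient_stats(p, lambda)
    stats2 <- new_sufficient_stats(p, lambda)
    th1 <- matrix(0, p, K)
    th2 <- matrix(0, p, K)
    theta1 <- numeric(p)
    theta2 <- numeric(p)
    log_rows <- vector("list", 2L * K)
    for (k in seq_len(K)) {
      d1 <- build_decoding_design(neural_pad, trial$stimuli$envelope1,
                                  k, W, L)
      d2 <- list(X = d1$X, y = trial$stimuli$envelope2[((k - 1L) * W + 1L):
                                                         (k * W)],
                 k = k, mode = "decoding")
      if (!is.null(G)) {
        d1$X <- d1$X %*% G
        d2$X <- d1$X
      }
      stats1 <- update_sufficient_stats(stats1, d1)
      stats2 <- update_sufficient_stats(stats2, d2)
      s1 <- fbs_solve(stats1, gamma, theta1, max_iter, tol, rel_tol)
      s2 <- fbs_solve(stats2, gamma, theta2, max_iter, tol, rel_tol)
      theta1 <- s1$theta
      theta2 <- s2$theta
      th1[, k] <- theta1
      th2[, k] <- theta2
      log_rows[[2L * k - 1L]] <- tibble::tibble(
        k = k, speaker = 1L, iterations = s1$solver_info$iterations,
        objective = s1$objective, kkt = s1$solver_info$kkt_residual)
      log_rows[[2L * k]] <- tibble::tibble(
        k = k, speaker = 2L, iterations = s2$solver_info$iterations,
        objective = s2$objective, kkt = s2$solver_info$kkt_residual)
    }
    eff <- list(
      if (is.null(G)) th1 else G %*% th1,
      if (is.null(G)) th2 else G %*% th2
    )
    theta <- list(th1, th2)
  } else {
    p_raw <- 1L + 2L * (L + 1L)
    p <- if (is.null(G)) p_raw else ncol(G)
    stats <- new_sufficient_stats(p, lambda)
    th <- matrix(0, p, K)
    theta <- numeric(p)
    log_rows <- vector("list", K)
    for (k in seq_len(K)) {
      d <- build_encoding_design(trial$stimuli, trial$neural, k, W, L)
      if (!is.null(G)) d$X <- d$X %*% G
      stats <- update_sufficient_stats(stats, d)
      s <- fbs_solve(stats, gamma, theta, max_iter, tol, rel_tol)
      theta <- s$theta
      th[, k] <- theta
      log_rows[[k]] <- tibble::tibble(
        k = k, speaker = NA_integer_,
        iterations = s$solver_info$iterations,
        objective = s$objective, kkt = s$solver_info$kkt_residual)
    }
    eff_full <- if (is.null(G)) th else G %*% th
    # split the stacked encoding vector into per-speaker TRFs
    eff <- list(
      eff_full[c(1L, 1L + seq_len(L + 1L)), , drop = FALSE],
      eff_full[c(1L, 1L + L + 1L + seq_len(L + 1L)), , drop = FALSE]
    )
    theta <- list(th, th)
  }

  structure(
    list(theta = theta, effective = eff,
         solver_log = dplyr::bind_rows(log_rows),
         mode = mode, fs = fs, W = as.integer(W), L = as.integer(L),
         lambda = lambda, gamma = gamma, dictionary = dictionary, K = K),
    class = "aad_coef_stream"
  )
}

#' Lag-domain coefficients for one speaker and window
#'
#' @param stream An `aad_coef_stream`.
#' @param speaker 1 or 2.
#' @param k Window index.
#' @param drop_intercept Drop the leading intercept coordinate
#'   (default TRUE).
#' @return Numeric vector over the lag grid.
#' @export
effective_coefficients <- function(stream, speaker, k,
                                   drop_intercept = TRUE) {
  v <- stream$effective[[speaker]][, k]
  if (drop_intercept) v[-1L] else v
}

#' @export
tidy.aad_coef_stream <- function(x, ...) {
  lag_s <- c(NA_real_, (0:x$L) / x$fs)
  purrr::map_dfr(1:2, function(sp) {
    m <- x$effective[[sp]]
    tibble::tibble(
      k = rep(seq_len(x$K), each = nrow(m)),
      t_s = rep(seq_len(x$K) * x$W / x$fs, each = nrow(m)),
      speaker = sp,
      lag_s = rep(lag_s, x$K),
      value = as.numeric(m)
    )
  })
}

#' @export
glance.aad_coef_stream <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, K = x$K, W = x$W, L = x$L,
    lambda = x$lambda, gamma = x$gamma,
    effective_length_s = effective_data_length_s(x$W, x$lambda, x$fs),
    mean_iterations = mean(x$solver_log$iterations),
    max_kkt = max(x$solver_log$kkt)
  )
}
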