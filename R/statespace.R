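#' Fixed-lag smoothing configuration
#'
#' The active sliding window has length `K_A = K_B + K_F + 1` instances,
#' where `K_F` is the forward lag (instances of future markers used) and
#' `K_B` the backward lag.
#'
#' @param K_A Active window length in instances.
#' @param K_F Forward lag in instances.
#' @param outer_iters Outer EM iterations (observation-model updates).
#' @param inner_iters Inner EM iterations (state-variance updates).
#' @return Object of class `aad_fixedlag_config` with fields `K_A`, `K_B`,
#'   `K_F`, `outer_iters`, `inner_iters`.
#' @export
fixed_lag_config <- function(K_A, K_F, outer_iters = 20L,
                             inner_iters = 1L) {
  K_A <- as.integer(K_A)
  K_F <- as.integer(K_F)
  K_B <- K_A - K_F - 1L
  if (K_B < 0L || K_F < 0L) {
    stop("need K_A >= K_F + 1 and K_F >= 0", call. = FALSE)
  }
  structure(
    list(K_A = K_A, K_B = K_B, K_F = K_F,
         outer_iters = as.integer(outer_iters),
         inner_iters = as.integer(inner_iters)),
    class = "aad_fixedlag_config"
  )
}

# numerically safe log(1 + exp(z))
.log1pexp <- function(z) {
  pmax(z, 0) + log1p(exp(-abs(z)))
}

#' Posterior probability of attending to speaker 1
#'
#' `P(n = 1 | m1, m2, z)` under the Log-Normal mixture observation model,
#' computed in log-space: the prior log-odds `z` plus the log-density
#' ratio of the two labellings.
#'
#' @param m1,m2 Positive marker values (vectors allowed).
#' @param z Latent state(s) (logit prior probability).
#' @param params An [ss_params()].
#' @return Responsibilities in `(0, 1)`.
#' @export
responsibilities <- function(m1, m2, z, params) {
  l1 <- lognormal_logpdf(m1, params$attended$rho, params$attended$mu) +
    lognormal_logpdf(m2, params$unattended$rho, params$unattended$mu)
  l2 <- lognormal_logpdf(m1, params$unattended$rho, params$unattended$mu) +
    lognormal_logpdf(m2, params$attended$rho, params$attended$mu)
  # clamp away from exact 0/1 so downstream log-space updates stay finite
  pmin(pmax(stats::plogis(z + l1 - l2), 1e-12), 1 - 1e-12)
}

# --- tridiagonal linear algebra (symmetric, positive definite) ----------

# Thomas algorithm: solve T x = rhs with diagonal d, off-diagonal e
.tri_solve <- function(d, e, rhs) {
  n <- length(d)
  if (n == 1L) return(rhs / d)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  cp[1L] <- e[1L] / d[1L]
  dp[1L] <- rhs[1L] / d[1L]
  for (i in 2:n) {
    m <- d[i] - (if (i > 1L) e[i - 1L] * cp[i - 1L] else 0)
    if (i < n) cp[i] <- e[i] / m
    dp[i] <- (rhs[i] - e[i - 1L] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# diagonal and first superdiagonal of the inverse of a SPD tridiagonal
# matrix, via the forward/backward Schur-complement recursions:
# (T^-1)_{ii} = 1 / (delta_i + beta_i - d_i),
# (T^-1)_{i,i+1} = -e_i (T^-1)_{ii} / beta_{i+1}.
.tri_inv_diag <- function(d, e) {
  n <- length(d)
  if (n == 1L) return(list(diag = 1 / d, offdiag = numeric(0)))
  delta <- numeric(n)
  beta <- numeric(n)
  delta[1L] <- d[1L]
  for (i in 2:n) delta[i] <- d[i] - e[i - 1L]^2 / delta[i - 1L]
  beta[n] <- d[n]
  for (i in (n - 1L):1L) beta[i] <- d[i] - e[i]^2 / beta[i + 1L]
  sdiag <- 1 / (delta + beta - d)
  soff <- -e * sdiag[-n] / beta[-1L]
  list(diag = sdiag, offdiag = soff)
}

# --- Laplace E-step: MAP trajectory of the logistic chain ---------------

# Maximise sum_k [r_k z_k - log(1+e^{z_k})] - sum_k (z_k - c0 z_{k-1})^2 /
# (2 eta_k) over z_{1:n} with z_0 fixed, by damped Newton iterations on the
# tridiagonal system. Returns the mode, the Laplace covariance diagonal and
# first off-diagonal, and the achieved gradient norm.
.z_map <- function(r, eta, z0, z_init, c0, max_newton = 50L,
                   gtol = 1e-8) {
  n <- length(r)
  z <- z_init
  fobj <- function(z) {
    zprev <- c(z0, z[-n])
    sum(r * z - .log1pexp(z)) - sum((z - c0 * zprev)^2 / (2 * eta))
  }
  f <- fobj(z)
  for (it in seq_len(max_newton)) {
    p <- stats::plogis(z)
    zprev <- c(z0, z[-n])
    g <- r - p - (z - c0 * zprev) / eta
    if (n > 1L) {
      g[-n] <- g[-n] + c0 * (z[-1L] - c0 * z[-n]) / eta[-1L]
    }
    if (max(abs(g)) < gtol) break
    d <- p * (1 - p) + 1 / eta
    if (n > 1L) {
      d[-n] <- d[-n] + c0^2 / eta[-1L]
      e <- rep(-c0, n - 1L) / eta[-1L]
    } else {
      e <- numeric(0)
    }
    step <- .tri_solve(d, e, g)
    alpha <- 1
    repeat {
      z_new <- z + alpha * step
      f_new <- fobj(z_new)
      if (f_new >= f - 1e-12 || alpha < 1e-10) break
      alpha <- alpha / 2
    }
    if (alpha < 1e-10) break # Newton step rejected entirely
    z <- z_new
    f <- f_new
  }
  # final curvature at the mode
  p <- stats::plogis(z)
  d <- p * (1 - p) + 1 / eta
  if (n > 1L) {
    d[-n] <- d[-n] + c0^2 / eta[-1L]
    e <- rep(-c0, n - 1L) / eta[-1L]
  } else {
    e <- numeric(0)
  }
  S <- .tri_inv_diag(d, e)
  zprev <- c(z0, z[-n])
  g <- r - p - (z - c0 * zprev) / eta
  if (n > 1L) g[-n] <- g[-n] + c0 * (z[-1L] - c0 * z[-n]) / eta[-1L]
  list(z = z, var = S$diag, cov_off = S$offdiag, grad_norm = max(abs(g)))
}

# posterior-mode Inverse-Gamma update of one state variance given
# v = E[(z_k - c0 z_{k-1})^2]; posterior is IG(a0 + 1/2, b0 + v/2)
.eta_update <- function(v, a0, b0) {
  (b0 + v / 2) / (a0 + 3 / 2)
}

# E[(z_k - c0 z_{k-1})^2] under the Laplace posterior; z_0 is fixed
.eta_moments <- function(z, svar, soff, z0, c0) {
  n <- length(z)
  zprev <- c(z0, z[-n])
  v <- (z - c0 * zprev)^2 + svar
  if (n > 1L) {
    v[-1L] <- v[-1L] + c0^2 * svar[-n] - 2 * c0 * soff
  }
  v
}

#' Nested-EM inference over one active window
#'
#' Runs the nested EM algorithm over the state-space parameters for one
#' active window of markers: the E-step computes mixture responsibilities
#' at the current state trajectory, finds the MAP trajectory of the
#' logistic chain by Newton iterations on the tridiagonal-Hessian
#' objective, and takes the Gaussian (Laplace) approximation from the
#' negative inverse curvature; the M-steps apply the closed-form conjugate
#' updates (Inverse-Gamma posterior mode for the state variances,
#' Normal-Gamma posterior for the Log-Normal observation parameters, using
#' responsibility-weighted log-marker moments). The outer loop updates the
#' observation model, the inner loop the state variances.
#'
#' @param m1,m2 Marker vectors over the window (length `K_A`, shorter
#'   during startup).
#' @param params An [ss_params()] (initial values; updated in place).
#' @param config An [fixed_lag_config()] (iteration counts are used here).
#' @param z_init Initial state trajectory (scalar or vector).
#' @param z0 Fixed boundary state preceding the window (default 0).
#' @param eta_init Initial state variances (default prior mean
#'   `b0/(a0-1)`).
#' @param update_obs Update the Log-Normal observation parameters
#'   (default TRUE).
#'
#' @return List with `z` (posterior mean), `z_var`, `eta`,
#'   `responsibility`, `params` (updated), `grad_norm`.
#' @export
estimate_window <- function(m1, m2, params, config, z_init = 0, z0 = 0,
                            eta_init = NULL, update_obs = TRUE) {
  n <- length(m1)
  stopifnot(length(m2) == n, n >= 1L)
  c0 <- params$c0
  z <- rep_len(z_init, n)
  eta <- if (is.null(eta_init)) {
    rep(params$b0 / (params$a0 - 1), n)
  } else {
    rep_len(eta_init, n)
  }
  fit <- NULL
  for (outer in seq_len(config$outer_iters)) {
    r <- responsibilities(m1, m2, z, params)
    for (inner in seq_len(config$inner_iters)) {
      fit <- .z_map(r, eta, z0, z, c0)
      z <- fit$z
      v <- .eta_moments(z, fit$var, fit$cov_off, z0, c0)
      eta <- .eta_update(v, params$a0, params$b0)
    }
    fit <- .z_map(r, eta, z0, z, c0)
    z <- fit$z
    if (update_obs) {
      # responsibility-weighted pools: m1 attended with weight r, etc.
      x <- c(log(m1), log(m2))
      w_att <- c(r, 1 - r)
      w_un <- c(1 - r, r)
      fa <- .ng_update(x, w_att, params$priors$attended)
      fu <- .ng_update(x, w_un, params$priors$unattended)
      if (!is.null(fa)) params$attended <- fa
      if (!is.null(fu)) params$unattended <- fu
    }
  }
  r <- responsibilities(m1, m2, z, params)
  list(z = z, z_var = fit$var, eta = eta, responsibility = r,
       params = params, grad_norm = fit$grad_norm)
}

.trajectory_tibble <- function(k, t_s, z, z_var, resp, mode,
                               built_in_delay_s) {
  sdz <- sqrt(pmax(z_var, 0))
  structure(
    tibble::tibble(
      k = k, t_s = t_s,
      p = stats::plogis(z),
      ci_lo = stats::plogis(z - 1.645 * sdz),
      ci_hi = stats::plogis(z + 1.645 * sdz),
      z_mean = z, z_var = z_var,
      responsibility = resp
    ),
    mode = mode, built_in_delay_s = built_in_delay_s,
    class = c("aad_trajectory", class(tibble::tibble()))
  )
}

#' Batch-mode state-space estimation
#'
#' Applies the state-space model to all markers of a trial at once
#' (`K_A = K`), the benchmark against which the fixed-lag real-time
#' estimator is compared.
#'
#' @param markers An `aad_markers` tibble.
#' @param params0 Initial [ss_params()] (typically from
#'   [fit_lognormal_supervised()]).
#' @param outer_iters,inner_iters EM iteration counts (defaults 20/20).
#' @param update_obs Update observation parameters during EM.
#' @return An `aad_trajectory` tibble (attribute `mode = "batch"`).
#' @export
batch_estimate <- function(markers, params0, outer_iters = 20L,
                           inner_iters = 20L, update_obs = TRUE) {
  K <- nrow(markers)
  cfg <- fixed_lag_config(K, 0L, outer_iters, inner_iters)
  fit <- estimate_window(markers$m1, markers$m2, params0, cfg,
                         z_init = 0, z0 = 0, update_obs = update_obs)
  .trajectory_tibble(markers$k, markers$t_s, fit$z, fit$z_var,
                     fit$responsibility, "batch", 0)
}

#' Real-time (fixed-lag) state-space estimation
#'
#' Slides the active window one instance at a time. At position `k0` the
#' nested EM is run over the instances inside the window (estimates prior
#' to the window stay frozen and supply the chain boundary), the updated
#' parameter set initialises the next position, and the estimate at
#' `k* = k0 - K_F` is emitted. The built-in reporting delay is
#' `(L_d + K_F W)/fs` for decoding models and `K_F W / fs` for encoding
#' models.
#'
#' @param markers An `aad_markers` tibble.
#' @param params0 Initial [ss_params()].
#' @param config An [fixed_lag_config()] (real-time default: 20 outer, 1
#'   inner EM iteration).
#' @param L Model lag in samples used only to report the built-in delay
#'   (`L_d` for decoding; 0 for encoding).
#' @param update_obs Update observation parameters during EM.
#' @return An `aad_trajectory` tibble (attribute `mode = "realtime"`,
#'   attribute `built_in_delay_s`).
#' @export
realtime_estimate <- function(markers, params0, config, L = 0L,
                              update_obs = TRUE) {
  K <- nrow(markers)
  fs <- attr(markers, "fs")
  W <- attr(markers, "W")
  K_A <- config$K_A
  K_F <- config$K_F
  delay <- if (!is.null(fs) && !is.null(W)) {
    (L + K_F * W) / fs
  } else {
    NA_real_
  }
  params <- params0
  frozen_z <- numeric(K) # estimates fixed once they leave the window
  z_out <- numeric(K)
  var_out <- numeric(K)
  resp_out <- numeric(K)
  z_win <- numeric(0)
  eta_win <- numeric(0)
  eta_prior_mean <- params0$b0 / (params0$a0 - 1)
  fit <- NULL
  lo_prev <- 1L
  for (k0 in seq_len(K)) {
    lo <- max(1L, k0 - K_A + 1L)
    # slide the carried state: drop frozen instances, append the new one
    if (length(z_win) > 0L) {
      drop_n <- lo - lo_prev
      if (drop_n > 0L) {
        z_win <- z_win[-seq_len(drop_n)]
        eta_win <- eta_win[-seq_len(drop_n)]
      }
      z_win <- c(z_win, z_win[length(z_win)])
      eta_win <- c(eta_win, eta_prior_mean)
    } else {
      z_win <- 0
      eta_win <- eta_prior_mean
    }
    z0 <- if (lo > 1L) frozen_z[lo - 1L] else 0
    fit <- estimate_window(markers$m1[lo:k0], markers$m2[lo:k0], params,
                           config, z_init = z_win, z0 = z0,
                           eta_init = eta_win, update_obs = update_obs)
    params <- fit$params
    z_win <- fit$z
    eta_win <- fit$eta
    frozen_z[lo:k0] <- fit$z # positions that leave the window stay fixed
    kstar <- k0 - K_F
    if (kstar >= 1L) {
      idx <- kstar - lo + 1L
      if (idx >= 1L) {
        z_out[kstar] <- fit$z[idx]
        var_out[kstar] <- fit$z_var[idx]
        resp_out[kstar] <- fit$responsibility[idx]
      }
    }
    lo_prev <- lo
  }
  # trial end: emit the remaining forward-lag instances from the final
  # window's posterior
  if (K_F > 0L && !is.null(fit)) {
    lo <- max(1L, K - K_A + 1L)
    for (kstar in seq(max(1L, K - K_F + 1L), K)) {
      idx <- kstar - lo + 1L
      z_out[kstar] <- fit$z[idx]
      var_out[kstar] <- fit$z_var[idx]
      resp_out[kstar] <- fit$responsibility[idx]
    }
  }
  .trajectory_tibble(markers$k, markers$t_s, z_out, var_out, resp_out,
                     "realtime", delay)
}

#' Relative mean squared error between two state trajectories
#'
#' `MSE = (1/K) sum_k (logistic(z_k^(B)) - logistic(z_k^(R)))^2`, the
#' probability-scale discrepancy between the batch-mode benchmark and the
#' real-time estimator run on the same markers.
#'
#' @param traj_realtime,traj_batch `aad_trajectory` tibbles of equal
#'   length.
#' @return Scalar MSE.
#' @export
compute_mse <- function(traj_realtime, traj_batch) {
  if (nrow(traj_realtime) != nrow(traj_batch)) {
    stop("trajectories have different lengths", call. = FALSE)
  }
  mean((stats::plogis(traj_batch$z_mean) -
          stats::plogis(traj_realtime$z_mean))^2)
}

#' Classify instances against ground truth with the CI convention
#'
#' Orients each instance's probability toward the attended speaker
#' (`p` if the truth is speaker 1, `1 - p` with swapped CI bounds
#' otherwise) and labels it correct if the whole 90% confidence interval
#' lies above 0.5, incorrect if it lies below, and unclassified otherwise.
#'
#' @param traj An `aad_trajectory`.
#' @param truth Integer vector (1/2) of attended speaker per instance, or a
#'   tibble with columns `k` and `attended`.
#' @param exclude Optional instance indices to skip (e.g. silence periods).
#' @return List with `hit_rate`, `false_alarm_rate`, `unclassified_rate`
#'   (over non-excluded instances) and `labels` tibble (`k`, `label`).
#' @export
classify_instances <- function(traj, truth, exclude = NULL) {
  if (is.data.frame(truth)) truth <- truth$attended[order(truth$k)]
  if (length(truth) != nrow(traj)) {
    stop("truth and trajectory lengths differ", call. = FALSE)
  }
  flip <- truth == 2L
  p <- ifelse(flip, 1 - traj$p, traj$p)
  lo <- ifelse(flip, 1 - traj$ci_hi, traj$ci_lo)
  hi <- ifelse(flip, 1 - traj$ci_lo, traj$ci_hi)
  label <- dplyr::case_when(
    lo > 0.5 ~ "correct",
    hi < 0.5 ~ "incorrect",
    TRUE ~ "unclassified"
  )
  keep <- rep(TRUE, nrow(traj))
  if (!is.null(exclude)) keep[exclude] <- FALSE
  n <- sum(keep)
  list(
    hit_rate = sum(label == "correct" & keep) / n,
    false_alarm_rate = sum(label == "incorrect" & keep) / n,
    unclassified_rate = sum(label == "unclassified" & keep) / n,
    labels = tibble::tibble(k = traj$k, label = label,
                            excluded = !keep)
  )
}

#' @export
tidy.aad_trajectory <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.aad_trajectory <- function(x, ...) {
  tibble::tibble(
    mode = attr(x, "mode"),
    K = nrow(x),
    built_in_delay_s = attr(x, "built_in_delay_s"),
    mean_p = mean(x$p),
    mean_ci_width = mean(x$ci_hi - x$ci_lo)
  )
}
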