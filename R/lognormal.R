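#' Log-Normal log-density in precision parameterisation
#'
#' `ln P(m) = -ln m + (1/2) ln rho - (rho/2)(ln m - mu)^2 - (1/2) ln(2 pi)`,
#' i.e. `log m ~ N(mu, 1/rho)` with `rho` the precision.
#'
#' @param m Positive observation(s).
#' @param rho Precision (> 0).
#' @param mu Log-scale mean.
#' @return Log-density value(s).
#' @export
lognormal_logpdf <- function(m, rho, mu) {
  if (any(m <= 0)) stop("`m` must be positive", call. = FALSE)
  if (rho <= 0) stop("`rho` must be positive", call. = FALSE)
  -log(m) + 0.5 * log(rho) - (rho / 2) * (log(m) - mu)^2 -
    0.5 * log(2 * pi)
}

#' State-space model parameters
#'
#' Bundles the transition scale, the Inverse-Gamma hyperparameters on the
#' state variances, the attended/unattended Log-Normal observation
#' parameters and their Normal-Gamma prior hyperparameters.
#'
#' @param c0 Transition scale in `[0, 1]` (default 1).
#' @param a0,b0 Inverse-Gamma hyperparameters (`a0` greater than and close
#'   to 2; defaults 2.008 and 0.2016 give prior mean 0.2 and variance 5).
#' @param attended,unattended Lists `list(rho = , mu = )`.
#' @param priors List with elements `attended` and `unattended`, each
#'   `list(alpha0, beta0, mu0, kappa0)` (Normal-Gamma hyperparameters).
#' @return Object of class `aad_ss_params`.
#' @export
ss_params <- function(c0 = 1, a0 = 2.008, b0 = 0.2016,
                      attended = list(rho = 1, mu = 0),
                      unattended = list(rho = 1, mu = 0),
                      priors = NULL) {
  if (c0 < 0 || c0 > 1) stop("`c0` must lie in [0, 1]", call. = FALSE)
  if (a0 <= 2) stop("`a0` must be greater than 2", call. = FALSE)
  if (b0 <= 0) stop("`b0` must be positive", call. = FALSE)
  if (is.null(priors)) {
    flat <- list(alpha0 = 0, beta0 = 0, mu0 = 0, kappa0 = 0)
    priors <- list(attended = flat, unattended = flat)
  }
  structure(
    list(c0 = c0, a0 = a0, b0 = b0, attended = attended,
         unattended = unattended, priors = priors),
    class = "aad_ss_params"
  )
}

#' Moments of the Inverse-Gamma state-variance prior
#'
#' @param a0,b0 Inverse-Gamma hyperparameters.
#' @return Tibble with `mean` (`b0/(a0-1)`, needs `a0 > 1`) and `variance`
#'   (`b0^2 / ((a0-1)^2 (a0-2))`, needs `a0 > 2`).
#' @export
inverse_gamma_moments <- function(a0, b0) {
  tibble::tibble(
    mean = if (a0 > 1) b0 / (a0 - 1) else NA_real_,
    variance = if (a0 > 2) b0^2 / ((a0 - 1)^2 * (a0 - 2)) else NA_real_
  )
}

# weighted Normal-Gamma conjugate update on log-observations.
# Returns posterior-based estimates: mu = mu_n, rho = alpha_n / beta_n
# (posterior mean; reduces to the ML precision n/S under flat priors).
.ng_update <- function(x, w, prior, rho_max = 1e6) {
  n_w <- sum(w)
  if (n_w <= 0) return(NULL)
  xbar <- sum(w * x) / n_w
  S <- sum(w * (x - xbar)^2)
  kn <- prior$kappa0 + n_w
  mun <- (prior$kappa0 * prior$mu0 + n_w * xbar) / kn
  an <- prior$alpha0 + n_w / 2
  bn <- prior$beta0 + S / 2 +
    prior$kappa0 * n_w * (xbar - prior$mu0)^2 / (2 * kn)
  rho <- if (bn > 0) an / bn else rho_max
  list(rho = min(rho, rho_max), mu = mun)
}

#' Supervised fit of the Log-Normal observation model
#'
#' Pools the marker values by their known attended/unattended role and
#' fits `(rho, mu)` for each pool by the conjugate Normal-Gamma update on
#' the log-markers (which reduces to maximum likelihood under flat priors).
#' The returned parameter set also carries prior hyperparameters re-centred
#' on the fits with inflated variances, so the smoother's own EM updates
#' are anchored but not over-constrained: the Gamma prior on `rho` is
#' moment-matched to mean `rho_hat` and variance `inflate * rho_hat^2`.
#'
#' Values equal to the positivity floor are excluded from the pools
#' before fitting (unless that would leave fewer than two values): floored
#' markers are logged degeneracies — e.g. the undefined correlation of an
#' all-zero warm-up decoder — and a single `log(1e-6)` outlier would
#' dominate the fitted log-scale variance.
#'
#' @param markers An `aad_markers` tibble (columns `m1`, `m2`).
#' @param labels Integer vector (1/2), the attended speaker per instance.
#' @param priors Optional `list(alpha0, beta0, mu0, kappa0)` applied to both
#'   pools during the fit (default flat).
#' @param inflate Prior variance inflation factor (default 10).
#' @param rho_max Precision cap for degenerate (zero-variance) pools.
#' @param c0,a0,b0 Passed through to [ss_params()].
#' @return An `aad_ss_params`.
#' @export
fit_lognormal_supervised <- function(markers, labels, priors = NULL,
                                     inflate = 10, rho_max = 1e6,
                                     c0 = 1, a0 = 2.008, b0 = 0.2016) {
  if (length(labels) != nrow(markers)) {
    stop("`labels` must give the attended speaker per instance",
         call. = FALSE)
  }
  att <- c(markers$m1[labels == 1L], markers$m2[labels == 2L])
  un <- c(markers$m1[labels == 2L], markers$m2[labels == 1L])
  # flooring events (e.g. correlations of an all-zero warm-up decoder) are
  # logged degeneracies, not marker observations; a single log(floor)
  # outlier would dominate the fitted log-scale variance
  drop_floor <- function(x) {
    keep <- x > MARKER_FLOOR
    if (sum(keep) >= 2L) x[keep] else x
  }
  att <- drop_floor(att)
  un <- drop_floor(un)
  if (length(att) < 2L || length(un) < 2L) {
    stop("need at least 2 attended and 2 unattended marker values",
         call. = FALSE)
  }
  if (is.null(priors)) priors <- list(alpha0 = 0, beta0 = 0,
                                      mu0 = 0, kappa0 = 0)
  fa <- .ng_update(log(att), rep(1, length(att)), priors, rho_max)
  fu <- .ng_update(log(un), rep(1, length(un)), priors, rho_max)
  recentre <- function(fit) {
    list(alpha0 = 1 / inflate, beta0 = 1 / (inflate * fit$rho),
         mu0 = fit$mu, kappa0 = 1)
  }
  ss_params(
    c0 = c0, a0 = a0, b0 = b0,
    attended = fa, unattended = fu,
    priors = list(attended = recentre(fa), unattended = recentre(fu))
  )
}
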