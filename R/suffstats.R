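#' Initialise exponentially-weighted sufficient statistics
#'
#' The exponentially-weighted least-squares objective
#' `sum_j lambda^(k-j) ||y_j - X_j theta||^2` equals
#' `theta' A theta - 2 b' theta + c` with
#' `A = sum_j lambda^(k-j) X_j' X_j`, `b = sum_j lambda^(k-j) X_j' y_j` and
#' `c = sum_j lambda^(k-j) y_j' y_j`, which this state carries recursively.
#'
#' @param p Coefficient dimension.
#' @param lambda Forgetting factor in `(0, 1]`.
#' @return Object of class `aad_suffstats`.
#' @export
new_sufficient_stats <- function(p, lambda) {
  if (lambda <= 0 || lambda > 1) {
    stop("`lambda` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(A = matrix(0, p, p), b = numeric(p), c = 0,
         lam = lambda, k = 0L),
    class = "aad_suffstats"
  )
}

#' Absorb one window into the sufficient statistics
#'
#' `A <- lambda A + X'X`, `b <- lambda b + X'y`, `c <- lambda c + y'y`.
#' Windows must arrive in order (`window$k == stats$k + 1`).
#'
#' @param stats An `aad_suffstats`.
#' @param window A design window from [build_decoding_design()] /
#'   [build_encoding_design()] (any list with `X`, `y`, `k`).
#' @return Updated `aad_suffstats`.
#' @export
update_sufficient_stats <- function(stats, window) {
  if (window$k != stats$k + 1L) {
    stop(sprintf("out-of-order window: expected %d, got %d",
                 stats$k + 1L, window$k), call. = FALSE)
  }
  X <- window$X
  y <- window$y
  stats$A <- stats$lam * stats$A + crossprod(X)
  stats$b <- stats$lam * stats$b + drop(crossprod(X, y))
  stats$c <- stats$lam * stats$c + sum(y^2)
  stats$k <- window$k
  stats
}

#' Evaluate the regularised objective from sufficient statistics
#'
#' `theta' A theta - 2 b' theta + c + gamma ||theta||_1`, which equals the
#' direct exponentially-weighted sum of squared residuals plus the l1
#' penalty.
#'
#' @param stats An `aad_suffstats`.
#' @param theta Coefficient vector.
#' @param gamma l1 penalty weight (default 0: quadratic part only).
#' @return Scalar objective value.
#' @export
objective_from_stats <- function(stats, theta, gamma = 0) {
  drop(crossprod(theta, stats$A %*% theta)) - 2 * sum(stats$b * theta) +
    stats$c + gamma * sum(abs(theta))
}
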