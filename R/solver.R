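#' Soft-thresholding operator
#'
#' Componentwise `sign(v) * max(|v| - tau, 0)`, the proximal operator of
#' `tau * ||.||_1`.
#'
#' @param v Numeric vector.
#' @param tau Non-negative threshold.
#' @return Numeric vector of `length(v)`.
#' @export
soft_threshold <- function(v, tau) {
  if (tau < 0) stop("`tau` must be non-negative", call. = FALSE)
  sign(v) * pmax(abs(v) - tau, 0)
}

# largest eigenvalue of a symmetric PSD matrix by power iteration
.power_lmax <- function(A, iters = 30L) {
  p <- nrow(A)
  v <- rep(1 / sqrt(p), p)
  lmax <- 0
  for (i in seq_len(iters)) {
    w <- A %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- as.numeric(w / nw)
    lmax <- nw
  }
  lmax
}

#' Solve the exponentially-weighted LASSO by forward-backward splitting
#'
#' Minimises `theta' A theta - 2 b' theta + c + gamma ||theta||_1` over the
#' recursively accumulated sufficient statistics, using the proximal
#' gradient method with Nesterov momentum, a Barzilai-Borwein-style adaptive
#' step size and backtracking. The accepted iterate sequence is monotone in
#' the objective (a candidate step that would increase the objective falls
#' back to a plain monotone proximal step). Iteration stops once the
#' first-order (subgradient) optimality residual falls below `tol`:
#' every non-zero coordinate satisfies
#' `|2(A theta - b)_i + gamma sign(theta_i)| <= tol` and every zero
#' coordinate satisfies `|2(A theta - b)_i| <= gamma + tol`. Optionally a
#' relative-objective-change stopping rule (`rel_tol`) can be enabled for
#' real-time budgets.
#'
#' @param stats An `aad_suffstats` (or any list with `A`, `b`, `c`).
#' @param gamma Non-negative l1 weight.
#' @param theta_init Warm-start vector (default zeros).
#' @param max_iter Maximum iterations (default 500).
#' @param tol Subgradient optimality tolerance (default 1e-8).
#' @param rel_tol If > 0, additionally stop when the relative objective
#'   change between accepted iterates drops below this value (default 0,
#'   disabled).
#'
#' @return Object of class `aad_coefstate`: list with `theta`, `gamma`,
#'   `objective`, `solver_info` (list: `iterations`, `step`, `objective`,
#'   `kkt_residual`, `converged`).
#' @export
fbs_solve <- function(stats, gamma, theta_init = NULL, max_iter = 500L,
                      tol = 1e-8, rel_tol = 0) {
  if (gamma < 0) stop("`gamma` must be non-negative", call. = FALSE)
  A <- (stats$A + t(stats$A)) / 2
  b <- stats$b
  p <- length(b)
  # guard against numerically indefinite accumulated Gram matrices
  dmin <- suppressWarnings(min(eigen(A, symmetric = TRUE,
                                     only.values = TRUE)$values))
  if (!is.finite(dmin) || dmin < -1e-8 * max(1, sum(diag(A)))) {
    eps <- 1e-10 * sum(diag(A)) / max(1, p)
    warning("accumulated Gram matrix numerically indefinite; adding ",
            format(eps), " * I", call. = FALSE)
    A <- A + diag(eps, p)
  }
  theta <- if (is.null(theta_init)) numeric(p) else as.numeric(theta_init)

  fval <- function(th) {
    drop(crossprod(th, A %*% th)) - 2 * sum(b * th) + stats$c
  }
  Fval <- function(th) fval(th) + gamma * sum(abs(th))
  grad <- function(th) 2 * (A %*% th - b)

  kkt_residual <- function(th, g) {
    nz <- th != 0
    r <- numeric(p)
    r[nz] <- abs(g[nz] + gamma * sign(th[nz]))
    r[!nz] <- pmax(abs(g[!nz]) - gamma, 0)
    max(r, 0)
  }

  lmax <- .power_lmax(A)
  step <- if (lmax > 0) 1 / (2 * lmax) else 1
  v <- theta
  t_mom <- 1
  obj <- Fval(theta)
  g_th <- as.numeric(grad(theta))
  res <- kkt_residual(theta, g_th)
  it <- 0L
  theta_prev <- theta
  g_prev <- NULL

  # monotone FISTA: the accelerated candidate is always used to propagate
  # momentum, but the reported iterate never increases the objective
  while (it < max_iter && res > tol) {
    it <- it + 1L
    g_v <- as.numeric(grad(v))
    # Barzilai-Borwein step-size proposal from the last accepted pair
    if (!is.null(g_prev)) {
      dth <- theta - theta_prev
      dg <- g_th - g_prev
      denom <- sum(dth * dg)
      if (denom > 0) {
        bb <- sum(dth * dth) / denom
        if (is.finite(bb) && bb > 0) step <- bb
      }
    }
    f_v <- fval(v)
    # backtracking on the majorisation at the momentum point
    repeat {
      cand <- soft_threshold(v - step * g_v, step * gamma)
      dv <- cand - v
      if (fval(cand) <= f_v + sum(g_v * dv) + sum(dv^2) / (2 * step) ||
          step < 1e-14) break
      step <- step / 2
    }
    obj_cand <- Fval(cand)
    g_prev <- g_th
    theta_prev <- theta
    accepted <- if (obj_cand <= obj + 1e-12 * max(1, abs(obj))) {
      cand
    } else {
      theta
    }
    if (sum((v - cand) * (cand - theta_prev)) > 0) {
      # adaptive restart: momentum is pointing uphill
      t_mom <- 1
      v <- accepted
    } else {
      t_new <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
      v <- accepted + (t_mom / t_new) * (cand - accepted) +
        ((t_mom - 1) / t_new) * (accepted - theta_prev)
      t_mom <- t_new
    }
    theta <- accepted
    g_th <- as.numeric(grad(theta))
    obj_new <- Fval(theta)
    res <- kkt_residual(theta, g_th)
    if (rel_tol > 0 && abs(obj - obj_new) <= rel_tol * max(abs(obj), 1e-12)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  structure(
    list(theta = theta, gamma = gamma, objective = obj,
         solver_info = list(iterations = it, step = step, objective = obj,
                            kkt_residual = res, converged = res <= tol)),
    class = "aad_coefstate"
  )
}
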