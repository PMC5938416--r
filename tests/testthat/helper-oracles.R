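# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, closed forms and grid searches.

# cyclic coordinate-descent LASSO on the quadratic form
# theta' A theta - 2 b' theta + gamma ||theta||_1, run to high precision
cd_lasso_oracle <- function(A, b, gamma, iters = 50000L, tol = 1e-12) {
  p <- length(b)
  th <- numeric(p)
  for (it in seq_len(iters)) {
    old <- th
    for (i in seq_len(p)) {
      r <- b[i] - sum(A[i, -i] * th[-i])
      th[i] <- sign(r) * max(abs(r) - gamma / 2, 0) / A[i, i]
    }
    if (max(abs(th - old)) < tol) break
  }
  th
}

# double-loop evaluation of the convolutional generative model
brute_decoding_response <- function(s1, s2, h, w1, w2, mu, u) {
  n <- length(s1)
  L <- length(h) - 1L
  e <- numeric(n)
  for (t in seq_len(n)) {
    acc1 <- 0
    acc2 <- 0
    for (l in 0:L) {
      if (t - l >= 1L) {
        acc1 <- acc1 + h[l + 1L] * s1[t - l]
        acc2 <- acc2 + h[l + 1L] * s2[t - l]
      }
    }
    e[t] <- w1[t] * acc1 + w2[t] * acc2 + mu + u[t]
  }
  e
}

# direct evaluation of the exponentially weighted objective
# sum_j lambda^(k-j) ||y_j - X_j theta||^2 over a list of (X, y) windows
direct_weighted_objective <- function(windows, lambda, theta) {
  k <- length(windows)
  total <- 0
  for (j in seq_len(k)) {
    r <- windows[[j]]$y - windows[[j]]$X %*% theta
    total <- total + lambda^(k - j) * sum(r^2)
  }
  total
}

log1pexp_oracle <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# log posterior of the logistic chain with mixture observations and fixed
# state variances / observation parameters
chain_logpost <- function(z, m1, m2, params, eta, z0) {
  la1 <- rtaad::lognormal_logpdf(m1, params$attended$rho,
                                 params$attended$mu) +
    rtaad::lognormal_logpdf(m2, params$unattended$rho,
                            params$unattended$mu)
  la2 <- rtaad::lognormal_logpdf(m1, params$unattended$rho,
                                 params$unattended$mu) +
    rtaad::lognormal_logpdf(m2, params$attended$rho, params$attended$mu)
  p <- stats::plogis(z)
  obs <- sum(log(p * exp(la1 - pmax(la1, la2)) +
                   (1 - p) * exp(la2 - pmax(la1, la2))) + pmax(la1, la2))
  zprev <- c(z0, z[-length(z)])
  obs - sum((z - params$c0 * zprev)^2 / (2 * eta))
}

# iterated coordinate-wise dense grid ascent of the chain log posterior:
# a coarse global stage over [-grid_lim, grid_lim], then local grid
# refinement around the coarse fixed point (still pure grid evaluation)
grid_map_oracle <- function(m1, m2, params, eta, z0, grid_lim = 8,
                            grid_step = 0.01, sweeps = 60L) {
  n <- length(m1)
  sweep_over <- function(z, grids) {
    for (k in seq_len(n)) {
      vals <- vapply(grids[[k]], function(g) {
        zz <- z
        zz[k] <- g
        chain_logpost(zz, m1, m2, params, eta, z0)
      }, numeric(1))
      z[k] <- grids[[k]][which.max(vals)]
    }
    z
  }
  grid <- seq(-grid_lim, grid_lim, by = grid_step)
  z <- numeric(n)
  for (s in seq_len(sweeps)) {
    z_new <- sweep_over(z, rep(list(grid), n))
    if (identical(z_new, z)) break
    z <- z_new
  }
  for (s in seq_len(200L)) {
    local <- lapply(z, function(zi) seq(zi - 0.03, zi + 0.03, by = 5e-4))
    z_new <- sweep_over(z, local)
    if (max(abs(z_new - z)) < 1e-6) break
    z <- z_new
  }
  z
}

# markers drawn from the Log-Normal observation model itself
simulate_markers <- function(K, truth, params, fs = 200, W = 50,
                             seed = 1L) {
  set.seed(seed)
  draw <- function(n, rho, mu) exp(stats::rnorm(n, mu, 1 / sqrt(rho)))
  m1 <- ifelse(truth == 1L,
               draw(K, params$attended$rho, params$attended$mu),
               draw(K, params$unattended$rho, params$unattended$mu))
  m2 <- ifelse(truth == 2L,
               draw(K, params$attended$rho, params$attended$mu),
               draw(K, params$unattended$rho, params$unattended$mu))
  rtaad::new_markers(
    tibble::tibble(k = seq_len(K), t_s = seq_len(K) * W / fs,
                   m1 = m1, m2 = m2),
    marker_type = "correlation", fs = fs, W = W
  )
}
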