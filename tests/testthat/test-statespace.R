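test_that("responsibilities follow the density-ratio formula", {
  prm <- ss_params(attended = list(rho = 4, mu = 0),
                   unattended = list(rho = 4, mu = -1))
  # full symmetry
  expect_equal(responsibilities(0.3, 0.3, 0, prm), 0.5)
  # uninformative observations reduce to the prior logistic
  prm_eq <- ss_params(attended = list(rho = 2, mu = -0.5),
                      unattended = list(rho = 2, mu = -0.5))
  for (z in c(-2, 0, 1.3)) {
    expect_equal(responsibilities(0.8, 0.1, z, prm_eq), plogis(z))
  }
  # hand-set arithmetic oracle
  m1 <- 0.9
  m2 <- 0.2
  z <- 0.4
  fa <- function(m) exp(lognormal_logpdf(m, 4, 0))
  fu <- function(m) exp(lognormal_logpdf(m, 4, -1))
  p <- plogis(z)
  ref <- p * fa(m1) * fu(m2) /
    (p * fa(m1) * fu(m2) + (1 - p) * fu(m1) * fa(m2))
  expect_equal(responsibilities(m1, m2, z, prm), ref, tolerance = 1e-12)
  # normalisation: swapping the marker roles complements the probability
  expect_equal(responsibilities(m1, m2, z, prm) +
                 responsibilities(m2, m1, -z, prm), 1, tolerance = 1e-12)
})

test_that("state-variance update matches the conjugate closed form", {
  expect_equal(rtaad:::.eta_update(0, 2.008, 0.2016), 0.2016 / 3.508)
  expect_equal(rtaad:::.eta_update(0, 2.008, 0.2016), 0.05747,
               tolerance = 1e-4)
  v <- 0.3
  expect_equal(rtaad:::.eta_update(v, 2.008, 0.2016),
               (0.2016 + v / 2) / (2.008 + 1.5))
})

test_that("tridiagonal inverse recursions agree with dense inversion", {
  set.seed(9)
  for (n in c(1L, 2L, 5L, 30L)) {
    d <- runif(n, 2, 5)
    e <- if (n > 1) runif(n - 1, -0.8, 0.8) else numeric(0)
    Tm <- diag(d, n)
    if (n > 1) {
      Tm[cbind(1:(n - 1), 2:n)] <- e
      Tm[cbind(2:n, 1:(n - 1))] <- e
    }
    Sinv <- solve(Tm)
    res <- rtaad:::.tri_inv_diag(d, e)
    expect_equal(res$diag, diag(Sinv), tolerance = 1e-10)
    if (n > 1) {
      expect_equal(res$offdiag, Sinv[cbind(1:(n - 1), 2:n)],
                   tolerance = 1e-10)
    }
    rhs <- rnorm(n)
    expect_equal(rtaad:::.tri_solve(d, e, rhs), drop(solve(Tm, rhs)),
                 tolerance = 1e-10)
  }
})

test_that("symmetric evidence leaves the state at zero", {
  prm <- ss_params(attended = list(rho = 2, mu = 0),
                   unattended = list(rho = 2, mu = 0))
  cfg <- fixed_lag_config(8, 0, outer_iters = 10, inner_iters = 2)
  fit <- estimate_window(rep(0.5, 8), rep(0.5, 8), prm, cfg,
                         update_obs = FALSE)
  expect_equal(fit$z, rep(0, 8), tolerance = 1e-10)
  expect_equal(unname(plogis(fit$z)), rep(0.5, 8))
})

test_that("MAP trajectory matches the dense grid-search oracle", {
  prm <- ss_params(attended = list(rho = 6, mu = -0.5),
                   unattended = list(rho = 6, mu = -1.5))
  set.seed(31)
  for (rep_i in 1:3) {
    K_A <- sample(3:5, 1)
    truth <- sample(1:2, K_A, replace = TRUE)
    mk <- simulate_markers(K_A, truth, prm, seed = 100 + rep_i)
    cfg <- fixed_lag_config(K_A, 0, outer_iters = 40, inner_iters = 0)
    fit <- estimate_window(mk$m1, mk$m2, prm, cfg, update_obs = FALSE)
    eta_fixed <- rep(prm$b0 / (prm$a0 - 1), K_A)
    z_grid <- grid_map_oracle(mk$m1, mk$m2, prm, eta_fixed, z0 = 0)
    expect_lt(max(abs(fit$z - z_grid)), 0.02)
  }
})

test_that("strong constant evidence drives the posterior above 0.9", {
  prm <- ss_params(attended = list(rho = 25, mu = 0),
                   unattended = list(rho = 25, mu = -2))
  K_A <- 5L
  m1 <- rep(exp(0), K_A)    # squarely attended-like for speaker 1
  m2 <- rep(exp(-2), K_A)   # squarely unattended-like
  # state variances fixed at a level permitting the chain to move; the
  # check is the E-step MAP against the grid oracle
  cfg <- fixed_lag_config(K_A, 0, outer_iters = 30, inner_iters = 0)
  fit <- estimate_window(m1, m2, prm, cfg, eta_init = 4,
                         update_obs = FALSE)
  expect_true(all(plogis(fit$z[-1]) > 0.9)) # interior instances
  z_grid <- grid_map_oracle(m1, m2, prm, rep(4, K_A), z0 = 0)
  expect_lt(max(abs(fit$z - z_grid)), 0.02)
})

test_that("marker swap maps p to 1 - p and swaps the CI bounds", {
  prm <- ss_params(attended = list(rho = 6, mu = -0.3),
                   unattended = list(rho = 6, mu = -1.2))
  truth <- rep(c(1L, 2L), each = 15)
  mk <- simulate_markers(30, truth, prm, seed = 5)
  mk_swap <- mk
  mk_swap$m1 <- mk$m2
  mk_swap$m2 <- mk$m1
  bt <- batch_estimate(mk, prm)
  bts <- batch_estimate(mk_swap, prm)
  expect_equal(bts$p, 1 - bt$p, tolerance = 1e-8)
  expect_equal(bts$ci_lo, 1 - bt$ci_hi, tolerance = 1e-8)
  expect_equal(bts$ci_hi, 1 - bt$ci_lo, tolerance = 1e-8)
  cfg <- fixed_lag_config(10, 2)
  rt <- realtime_estimate(mk, prm, cfg)
  rts <- realtime_estimate(mk_swap, prm, cfg)
  expect_equal(rts$p, 1 - rt$p, tolerance = 1e-8)
  # probabilities and intervals stay inside (0, 1) in proper order
  for (tr in list(bt, rt)) {
    expect_true(all(tr$p > 0 & tr$p < 1))
    expect_true(all(tr$ci_lo > 0 & tr$ci_hi < 1))
    expect_true(all(tr$ci_lo <= tr$p & tr$p <= tr$ci_hi))
  }
})

test_that("monotone evidence strength yields monotone probabilities", {
  prm_strong <- ss_params(attended = list(rho = 9, mu = 0),
                          unattended = list(rho = 9, mu = -1.5))
  prm_weak <- ss_params(attended = list(rho = 9, mu = -0.5),
                        unattended = list(rho = 9, mu = -1.0))
  truth <- rep(1L, 25)
  # same log-marker noise realisation, different separations
  set.seed(12)
  eps1 <- rnorm(25, 0, 1 / 3)
  eps2 <- rnorm(25, 0, 1 / 3)
  build <- function(prm) {
    new_markers(
      tibble::tibble(k = 1:25, t_s = (1:25) / 4,
                     m1 = exp(prm$attended$mu + eps1),
                     m2 = exp(prm$unattended$mu + eps2)),
      "l1", 200, 50)
  }
  bt_strong <- batch_estimate(build(prm_strong), prm_strong,
                              update_obs = FALSE)
  bt_weak <- batch_estimate(build(prm_weak), prm_weak,
                            update_obs = FALSE)
  expect_true(all(bt_strong$p >= bt_weak$p - 1e-8))
})

test_that("full-window fixed-lag estimation agrees with batch", {
  prm <- ss_params(attended = list(rho = 6, mu = -0.3),
                   unattended = list(rho = 6, mu = -1.2))
  K <- 20L
  truth <- rep(c(1L, 2L), each = 10)
  mk <- simulate_markers(K, truth, prm, seed = 8)
  cfg <- fixed_lag_config(K, K - 1L, outer_iters = 20, inner_iters = 20)
  rt <- realtime_estimate(mk, prm, cfg, update_obs = FALSE)
  bt <- batch_estimate(mk, prm, update_obs = FALSE)
  expect_lt(compute_mse(rt, bt), 1e-3)
  expect_equal(rt$p, bt$p, tolerance = 0.02)
})

test_that("the relative MSE matches Eq.-style hand arithmetic", {
  mk_t <- function(z) {
    structure(tibble::tibble(k = seq_along(z), t_s = seq_along(z),
                             p = plogis(z), ci_lo = 0.1, ci_hi = 0.9,
                             z_mean = z, z_var = 0.1,
                             responsibility = 0.5),
              class = c("aad_trajectory", class(tibble::tibble())))
  }
  expect_equal(compute_mse(mk_t(c(1, -1)), mk_t(c(1, -1))), 0)
  expect_equal(compute_mse(mk_t(log(3)), mk_t(0)), 0.0625)
  set.seed(4)
  zb <- rnorm(10)
  zr <- rnorm(10)
  expect_equal(compute_mse(mk_t(zr), mk_t(zb)),
               mean((plogis(zb) - plogis(zr))^2))
  expect_error(compute_mse(mk_t(1:3), mk_t(1:2)), "lengths")
})

test_that("classification follows the confidence-interval convention", {
  traj <- structure(
    tibble::tibble(
      k = 1:3, t_s = 1:3,
      p = c(0.9, 0.55, 0.2),
      ci_lo = c(0.8, 0.45, 0.1),
      ci_hi = c(0.95, 0.65, 0.3),
      z_mean = 0, z_var = 0, responsibility = 0.5),
    class = c("aad_trajectory", class(tibble::tibble())))
  res <- classify_instances(traj, truth = c(1L, 1L, 1L))
  expect_equal(res$labels$label, c("correct", "unclassified", "incorrect"))
  expect_equal(res$hit_rate, 1 / 3)
  expect_equal(res$false_alarm_rate, 1 / 3)
  # orientation flips for truth = 2
  res2 <- classify_instances(traj, truth = c(2L, 2L, 2L))
  expect_equal(res2$labels$label,
               c("incorrect", "unclassified", "correct"))
  # excluded instances are skipped in the rates
  res3 <- classify_instances(traj, truth = c(1L, 1L, 1L), exclude = 2L)
  expect_equal(res3$hit_rate, 0.5)
  expect_equal(res3$unclassified_rate, 0)
})
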