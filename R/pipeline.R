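#' Effective data length of the forgetting-factor estimator
#'
#' `W / (1 - lambda)` samples, expressed in seconds: the effective number
#' of recent samples entering the exponentially-weighted estimate.
#'
#' @param W Window length in samples.
#' @param lambda Forgetting factor in `(0, 1)`.
#' @param fs Sampling rate in Hz.
#' @return Effective data length in seconds.
#' @export
effective_data_length_s <- function(W, lambda, fs) {
  if (lambda >= 1) return(Inf)
  W / (1 - lambda) / fs
}

#' Built-in attention-decoding delay
#'
#' `(L_d + K_F W)/fs` seconds for a decoding model (the decoder's future
#' lags add to the forward-lag reporting delay) and `K_F W / fs` for an
#' encoding model.
#'
#' @param mode `"decoding"` or `"encoding"`.
#' @param K_F Forward lag in instances.
#' @param W Window length in samples.
#' @param fs Sampling rate in Hz.
#' @param L_d Decoding lag in samples (ignored for encoding).
#' @return Delay in seconds.
#' @export
builtin_delay_s <- function(mode, K_F, W, fs, L_d = 0L) {
  mode <- match.arg(mode, c("decoding", "encoding"))
  if (mode == "decoding") (L_d + K_F * W) / fs else K_F * W / fs
}

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483587)
}

#' Experiment configuration
#'
#' Collects all pipeline hyperparameters with the study defaults: 60 s
#' dual-speaker trials at 200 Hz, 0.25 s windows (`W = 50`, `K = 240`
#' instances), decoder lag 0.4 s (`L_d = 80`), forgetting factor 0.95 and
#' l1 weight 0.001 for decoding; active smoothing window `floor(15 fs/W)`
#' instances with forward lag `floor(1.5 fs/W)`; Inverse-Gamma state
#' variance prior `a0 = 2.008`, `b0 = 0.2016`. Encoding mode switches to
#' `lambda = 0.975` with the Gaussian TRF dictionary enabled.
#'
#' @param mode `"eeg_decoding"` or `"meg_encoding"`.
#' @param marker_type `"correlation"`, `"l1"` or `"m100"` (default:
#'   correlation for decoding, m100 for encoding).
#' @param fs,duration_s,W,L,lambda,gamma,case_id,switch_times_s,noise_var
#'   Generator and estimator settings (see Details and the module
#'   functions).
#' @param K_A_s,K_F_s Active window and forward lag in seconds.
#' @param a0,b0,c0 State-space hyperparameters.
#' @param dictionary_enabled,dictionary_std_s,dictionary_spacing_s Gaussian
#'   dictionary settings (encoding only by default).
#' @param solver_tol,solver_rel_tol,solver_max_iter FBS settings.
#' @param tuning_duration_s Length of the supervised tuning trial.
#' @param outer_iters,inner_iters Real-time EM iteration counts.
#' @return Object of class `aad_config` (a named list with derived fields
#'   `K`, `K_A`, `K_F`).
#' @export
aad_config <- function(mode = c("eeg_decoding", "meg_encoding"),
                       marker_type = NULL,
                       fs = 200, duration_s = 60, W = 50L, L = 80L,
                       lambda = NULL, gamma = NULL,
                       case_id = 1L, switch_times_s = 30,
                       noise_var = 2.5e-5,
                       K_A_s = 15, K_F_s = 1.5,
                       a0 = 2.008, b0 = 0.2016, c0 = 1,
                       dictionary_enabled = NULL,
                       dictionary_std_s = 0.020,
                       dictionary_spacing_s = 0.005,
                       solver_tol = 1e-8, solver_rel_tol = 0.01,
                       solver_max_iter = 500L,
                       tuning_duration_s = 15,
                       outer_iters = 20L, inner_iters = 1L) {
  mode <- match.arg(mode)
  est_mode <- if (mode == "eeg_decoding") "decoding" else "encoding"
  if (is.null(lambda)) lambda <- if (est_mode == "decoding") 0.95 else 0.975
  if (is.null(gamma)) gamma <- if (est_mode == "decoding") 0.001 else 0.01
  if (is.null(marker_type)) {
    marker_type <- if (est_mode == "decoding") "correlation" else "m100"
  }
  if (is.null(dictionary_enabled)) {
    dictionary_enabled <- est_mode == "encoding"
  }
  cfg <- list(
    mode = mode, est_mode = est_mode, marker_type = marker_type,
    fs = fs, duration_s = duration_s, W = as.integer(W), L = as.integer(L),
    lambda = lambda, gamma = gamma, case_id = case_id,
    switch_times_s = switch_times_s, noise_var = noise_var,
    K = floor(duration_s * fs / W),
    K_A = floor(K_A_s * fs / W), K_F = floor(K_F_s * fs / W),
    a0 = a0, b0 = b0, c0 = c0,
    dictionary_enabled = dictionary_enabled,
    dictionary_std_s = dictionary_std_s,
    dictionary_spacing_s = dictionary_spacing_s,
    solver_tol = solver_tol, solver_rel_tol = solver_rel_tol,
    solver_max_iter = as.integer(solver_max_iter),
    tuning_duration_s = tuning_duration_s,
    outer_iters = as.integer(outer_iters),
    inner_iters = as.integer(inner_iters)
  )
  structure(cfg, class = "aad_config")
}

#' Simulate a complete dual-speaker trial under a configuration
#'
#' Draws fresh envelopes, attention weights (decoding) or a truth schedule
#' (encoding), and the neural response, with all sub-seeds derived
#' deterministically from `seed`.
#'
#' @param config An [aad_config()].
#' @param seed Integer master seed.
#' @param duration_s Override of the configured duration (used for tuning
#'   trials).
#' @param switch_times_s Override of the configured switch times.
#' @return An `aad_sim_trial`.
#' @export
simulate_trial <- function(config, seed, duration_s = config$duration_s,
                           switch_times_s = config$switch_times_s) {
  fs <- config$fs
  env1 <- make_speechlike_envelope(duration_s, fs,
                                   seed = derive_seed(seed, 1L))
  env2 <- make_speechlike_envelope(duration_s, fs,
                                   seed = derive_seed(seed, 2L))
  stim <- stimulus_pair(env1, env2, fs)
  if (config$est_mode == "decoding") {
    kern <- make_trf_kernel(fs)
    wts <- make_attention_weights(duration_s, fs, switch_times_s,
                                  case_id = config$case_id,
                                  seed = derive_seed(seed, 3L))
    simulate_decoding_trial(stim, kern, wts,
                            noise_var = config$noise_var,
                            seed = derive_seed(seed, 4L), W = config$W)
  } else {
    n <- round(duration_s * fs)
    t_s <- (seq_len(n) - 0.5) / fs
    flips <- vapply(t_s, function(t) sum(switch_times_s <= t), integer(1))
    sched <- ifelse(flips %% 2L == 0L, 1L, 2L)
    ka <- make_trf_kernel(fs)
    ku <- make_trf_kernel(fs, default_unattended_trf_components())
    simulate_encoding_trial(stim, ka, ku, sched,
                            noise_var = config$noise_var,
                            seed = derive_seed(seed, 4L), W = config$W)
  }
}

.config_dictionary <- function(config) {
  if (!config$dictionary_enabled) return(NULL)
  make_gaussian_dictionary(config$fs, lag_max_s = config$L / config$fs,
                           kernel_std_s = config$dictionary_std_s,
                           spacing_s = config$dictionary_spacing_s)
}

#' Coefficients and markers for one trial under a configuration
#'
#' @param trial An `aad_sim_trial`.
#' @param config An [aad_config()].
#' @return List with `stream` (`aad_coef_stream`) and `markers`
#'   (`aad_markers`).
#' @export
trial_markers <- function(trial, config) {
  stream <- estimate_coefficients(
    trial, mode = config$est_mode, lambda = config$lambda,
    gamma = config$gamma, W = config$W, L = config$L,
    dictionary = .config_dictionary(config),
    tol = config$solver_tol, rel_tol = config$solver_rel_tol,
    max_iter = config$solver_max_iter
  )
  list(stream = stream,
       markers = marker_stream(stream, trial, config$marker_type))
}

#' Supervised tuning step
#'
#' Generates a short constant-attention sample trial (speaker 1 attended
#' throughout), runs the estimator and marker stages on it, and fits the
#' Log-Normal observation model with known labels.
#'
#' @param config An [aad_config()].
#' @param seed Integer master seed (a tuning-specific sub-seed is derived).
#' @return An [ss_params()].
#' @export
tune_observation_model <- function(config, seed) {
  tune_trial <- simulate_trial(config, derive_seed(seed, 77L),
                               duration_s = config$tuning_duration_s,
                               switch_times_s = numeric())
  tm <- trial_markers(tune_trial, config)
  fit_lognormal_supervised(tm$markers,
                           labels = rep(1L, nrow(tm$markers)),
                           c0 = config$c0, a0 = config$a0, b0 = config$b0)
}

#' Run the full pipeline on one simulated trial
#'
#' simulate -> estimate coefficients -> markers -> supervised tuning ->
#' batch and real-time smoothing -> evaluation. If `out_dir` is given, all
#' intermediate tables are written (`stimuli.tsv`, `neural.tsv`,
#' `truth.tsv`, `meta.json`, `coefficients.tsv`, `solver_log.tsv`,
#' `markers.tsv`, `trajectory.tsv`, `summary.json`).
#'
#' @param config An [aad_config()].
#' @param seed Integer master seed; the run is deterministic given
#'   (config, seed).
#' @param out_dir Optional output directory.
#' @return List with `trial`, `stream`, `markers`, `params`, `batch`,
#'   `realtime`, `classification`, `mse_vs_batch`, `config`, `seed`.
#' @export
run_trial <- function(config, seed, out_dir = NULL) {
  trial <- simulate_trial(config, seed)
  tm <- trial_markers(trial, config)
  params0 <- tune_observation_model(config, seed)
  cfg_rt <- fixed_lag_config(config$K_A, config$K_F,
                             config$outer_iters, config$inner_iters)
  L_delay <- if (config$est_mode == "decoding") config$L else 0L
  rt <- realtime_estimate(tm$markers, params0, cfg_rt, L = L_delay)
  bt <- batch_estimate(tm$markers, params0)
  cls <- classify_instances(rt, trial$truth)
  mse <- compute_mse(rt, bt)
  out <- list(trial = trial, stream = tm$stream, markers = tm$markers,
              params = params0, batch = bt, realtime = rt,
              classification = cls, mse_vs_batch = mse,
              config = config, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trial(trial, out_dir)
    readr::write_tsv(generics::tidy(tm$stream),
                     file.path(out_dir, "coefficients.tsv"))
    readr::write_tsv(tm$stream$solver_log,
                     file.path(out_dir, "solver_log.tsv"))
    readr::write_tsv(tibble::as_tibble(tm$markers),
                     file.path(out_dir, "markers.tsv"))
    traj <- dplyr::bind_rows(
      dplyr::mutate(tibble::as_tibble(rt), mode = "realtime"),
      dplyr::mutate(tibble::as_tibble(bt), mode = "batch")
    )
    readr::write_tsv(traj, file.path(out_dir, "trajectory.tsv"))
    jsonlite::write_json(
      list(hit_rate = cls$hit_rate,
           false_alarm_rate = cls$false_alarm_rate,
           unclassified_rate = cls$unclassified_rate,
           mse_vs_batch = mse,
           built_in_delay_s = attr(rt, "built_in_delay_s"),
           seed = seed),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Forward-lag sweep
#'
#' For each forward lag, re-runs the real-time estimator on the same
#' marker series and measures the probability-scale MSE against the batch
#' benchmark, averaged over trials. The incremental MSE is the successive
#' difference (discrete derivative) of the mean MSE curve.
#'
#' @param markers_list List of `aad_markers` (one per trial/seed).
#' @param params_list List of [ss_params()] matching `markers_list`.
#' @param kf_values Integer vector of forward lags (instances).
#' @param K_A Active window length in instances.
#' @param L Model lag in samples (for the built-in delay report).
#' @param outer_iters,inner_iters Real-time EM iteration counts.
#' @return Tibble with `K_F`, `K_F_s`, `mean_mse`, `incremental_mse`.
#' @export
sweep_forward_lag <- function(markers_list, params_list, kf_values,
                              K_A, L = 0L, outer_iters = 20L,
                              inner_iters = 1L) {
  if (length(kf_values) < 2L) {
    stop("need at least two forward-lag values", call. = FALSE)
  }
  batches <- purrr::map2(markers_list, params_list, batch_estimate)
  mean_mse <- vapply(kf_values, function(kf) {
    cfg <- fixed_lag_config(max(K_A, kf + 1L), kf, outer_iters,
                            inner_iters)
    mses <- purrr::pmap_dbl(
      list(markers_list, params_list, batches),
      function(mk, pr, bt) {
        compute_mse(realtime_estimate(mk, pr, cfg, L = L), bt)
      }
    )
    mean(mses)
  }, numeric(1))
  fs <- attr(markers_list[[1]], "fs")
  W <- attr(markers_list[[1]], "W")
  tibble::tibble(
    K_F = as.integer(kf_values),
    K_F_s = kf_values * W / fs,
    mean_mse = mean_mse,
    incremental_mse = c(NA_real_, diff(mean_mse))
  )
}

#' Transition delay after an abrupt attention switch
#'
#' Measures, on the delay-calibrated probability trajectory, the time
#' after a step switch for the probability of attending the previously
#' attended speaker to cross 0.5 (the point at which the classification
#' label changes). The crossing time is linearly interpolated between
#' instances. The trajectory's `t_s` axis already refers to the instant
#' each estimate describes, so it is calibrated with respect to the
#' built-in delay; the report states both components and their total.
#'
#' @param traj An `aad_trajectory` (from [realtime_estimate()]).
#' @param switch_time_s Time of the step switch in seconds.
#' @param built_in_delay_s Built-in delay to report (default: the
#'   trajectory attribute).
#' @param pre_attended Speaker attended before the switch (default 1).
#' @return List (class `aad_delay_report`): `built_in_delay_s`,
#'   `transition_delay_s`, `total_delay_s`, `never_crossed`.
#' @export
measure_transition_delay <- function(traj, switch_time_s,
                                     built_in_delay_s =
                                       attr(traj, "built_in_delay_s"),
                                     pre_attended = 1L) {
  if (switch_time_s <= 0 || switch_time_s >= max(traj$t_s)) {
    stop("switch time outside the trial", call. = FALSE)
  }
  p <- if (pre_attended == 1L) traj$p else 1 - traj$p
  t <- traj$t_s
  after <- which(t >= switch_time_s)
  cross <- after[p[after] <= 0.5]
  if (length(cross) == 0L) {
    rep <- list(built_in_delay_s = built_in_delay_s,
                transition_delay_s = max(t) - switch_time_s,
                total_delay_s = built_in_delay_s + max(t) - switch_time_s,
                never_crossed = TRUE)
    class(rep) <- "aad_delay_report"
    return(rep)
  }
  i <- cross[1L]
  t_cross <- if (i > 1L && p[i - 1L] > 0.5) {
    # linear interpolation of the 0.5 crossing between instances
    t[i - 1L] + (t[i] - t[i - 1L]) * (p[i - 1L] - 0.5) /
      (p[i - 1L] - p[i])
  } else {
    t[i]
  }
  delay <- max(t_cross - switch_time_s, 0)
  rep <- list(built_in_delay_s = built_in_delay_s,
              transition_delay_s = delay,
              total_delay_s = built_in_delay_s + delay,
              never_crossed = FALSE)
  class(rep) <- "aad_delay_report"
  rep
}

#' Transition-delay study over seeded trials
#'
#' Runs the full pipeline over a set of seeds under the given
#' configuration and collects the per-trial transition delays of the
#' real-time estimator after the configured switch.
#'
#' @param config An [aad_config()] with a single switch time.
#' @param seeds Integer vector of master seeds.
#' @return Tibble with `seed`, `transition_delay_s`, `never_crossed`.
#' @export
transition_delay_study <- function(config, seeds) {
  purrr::map_dfr(seeds, function(s) {
    res <- run_trial(config, s)
    d <- measure_transition_delay(res$realtime, config$switch_times_s[1])
    tibble::tibble(seed = s,
                   transition_delay_s = d$transition_delay_s,
                   never_crossed = d$never_crossed)
  })
}
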