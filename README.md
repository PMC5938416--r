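# rtaad — real-time auditory attention decoding

In a two-speaker "cocktail party" scene, cortical M/EEG responses track
the slow amplitude envelope of the *attended* talker more strongly than
the ignored one. `rtaad` turns that effect into a streaming estimate of
*who the listener is attending to*, with statistically interpretable
uncertainty, from a single unfolding trial — the setting of
brain-computer interfaces and smart hearing aids, where training data
are scarce and decisions are needed at ~0.25 s resolution with ~2 s
total delay.

The pipeline has three modules:

1. **Sparse adaptive filtering.** Per window `k`, encoding/decoding
   coefficients solve the exponentially-weighted LASSO

   ```
   theta_k = argmin_theta  sum_{j<=k} lambda^(k-j) ||y_j - X_j theta||^2
                           + gamma ||theta||_1
   ```

   over recursively updated sufficient statistics, by a monotone FISTA
   (proximal-gradient / forward-backward splitting with Nesterov
   momentum, Barzilai-Borwein steps, backtracking and adaptive restart).
   `W/(1-lambda)` samples is the effective data length (5 s at the
   default `W = 50`, `fs = 200`, `lambda = 0.95`). A Gaussian dictionary
   (81 kernels, 20 ms std, 5 ms spacing over 0-0.4 s lags) yields smooth
   TRF estimates for encoding models.

2. **Attention markers.** Each window becomes one positive scalar per
   speaker: `|corr(envelope, reconstruction)|`, the decoder l1-norm
   (intercept excluded), or the magnitude of the negative M100 TRF peak
   near the 0.1 s lag.

3. **Fixed-lag state-space smoothing.** A logistic latent chain
   `z_k = c0 z_{k-1} + w_k`, `w_k ~ N(0, eta_k)`,
   `eta_k ~ Inv-Gamma(a0, b0)`, with Log-Normal mixture observations on
   the marker pairs, estimated by nested EM (Laplace E-step on the
   tridiagonal chain, conjugate closed-form M-steps) over a sliding
   window of `K_A = K_B + K_F + 1` instances. The forward lag `K_F`
   trades reporting delay for robustness; the built-in delay is
   `(L_d + K_F W)/fs` (decoding) or `K_F W / fs` (encoding).

A generative simulator of dual-speaker trials (speech-like envelopes, a
convolutional neural-response model with attention-modulated weights or
TRFs, known ground truth) makes the whole pipeline testable without
recordings.

## Worked example

```r
library(rtaad)

cfg <- aad_config("eeg_decoding", case_id = 1)  # 60 s trial, switch at 30 s
res <- run_trial(cfg, seed = 1)

res$classification[c("hit_rate", "false_alarm_rate", "unclassified_rate")]
#> $hit_rate
#> [1] 0.9208333
#> $false_alarm_rate
#> [1] 0
#> $unclassified_rate
#> [1] 0.07916667

res$mse_vs_batch
#> [1] 0.00227986

d <- measure_transition_delay(res$realtime, switch_time_s = 30)
d$built_in_delay_s; d$transition_delay_s
#> [1] 1.9
#> [1] 1.888759
```

On this strong-modulation trial, 92% of the 240 quarter-second instances
are classified toward the true attended speaker with the whole 90%
interval on the correct side of 0.5, none on the wrong side, and 8% left
unclassified; the real-time trajectory deviates from the batch benchmark
by a probability-scale MSE of 0.002; and after the abrupt switch at 30 s
the calibrated probability crosses 0.5 in about 1.9 s, on top of the
1.9 s built-in delay.

`autoplot(res$markers)` and `autoplot(res$realtime)` draw the marker
streams and the probability trajectory with its credible ribbon;
`tidy()`/`glance()` return tibbles for downstream analysis. A thin CLI
(`exec/rtaad`) exposes `simulate`, `decode`/`encode`, `markers`,
`smooth`, `evaluate`, `run-all` and `sweep-kf` over trial directories of
TSV/JSON files.

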