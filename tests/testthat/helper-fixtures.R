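# Shared fixtures, built in code and cached per test run.

fixture_env <- new.env(parent = emptyenv())

# Small preprocessed cohort for mechanics-level tests.
tiny_cohort <- function() {
  if (is.null(fixture_env$tiny))
    fixture_env$tiny <- generate_cohort(8, 3, 0.5, seed = 42)
  fixture_env$tiny
}

# A tiny model spec that trains in well under a second.
tiny_spec <- function(kind = "hybrid") {
  model_spec(kind,
             tcn = tcn_config(channels = 8, kernel_size = 2,
                              dilations = c(1, 2), dropout = 0.1),
             static_units = 8, head_units = 8, head_dropout = 0.1,
             lstm_units = 8)
}

# Brute-force causal dilated convolution (independent oracle).
conv_oracle <- function(x, W, b, dilation) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]; K <- dim(W)[3]
  T <- ncol(x)
  y <- matrix(0, Cout, T)
  for (co in seq_len(Cout)) {
    for (t in seq_len(T)) {
      acc <- b[co]
      for (k in seq_len(K)) {
        tt <- t - (k - 1) * dilation
        if (tt >= 1) for (ci in seq_len(Cin))
          acc <- acc + W[co, ci, k] * x[ci, tt]
      }
      y[co, t] <- acc
    }
  }
  y
}

# Straight transcription of the printed Adam recurrences for one scalar.
adam_oracle_trajectory <- function(theta0, grads, alpha = 0.001,
                                   beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  theta <- theta0; m <- 0; v <- 0
  out <- numeric(length(grads))
  for (t in seq_along(grads)) {
    g <- grads[t]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    m_hat <- m / (1 - beta1^t)
    v_hat <- v / (1 - beta2^t)
    theta <- theta - alpha * m_hat / (sqrt(v_hat) + eps)
    out[t] <- theta
  }
  out
}

# Steady-state amplitude of a filtered sinusoid (edges discarded).
sine_gain <- function(freq, fs, spec, n_sec = 4) {
  t <- seq(0, n_sec, by = 1 / fs)
  y <- zero_lag_butterworth(sin(2 * pi * freq * t), spec)
  core <- y[round(length(y) * 0.25):round(length(y) * 0.75)]
  (max(core) - min(core)) / 2
}
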