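# Shared fixtures: tiny deterministic objects built in code.

# A clean, jitter-free recording whose geometry is known exactly.
clean_recording <- function(seed = 1, n_cycles = 6, cadence = 100,
                            stance_fraction = 0.6) {
  simulate_recording(gait_profile(
    cadence_spm = cadence, stance_fraction = stance_fraction,
    n_cycles = n_cycles, asymmetry = 0, noise_sd = 0, drift_sd = 0,
    seed = seed
  ))
}

# A small model configuration for fast unit tests.
tiny_model_config <- function(architecture = "tcn_gru", seed = 1, ...) {
  model_config(
    architecture = architecture,
    tcn_channels = 4, tcn_kernel = 3, tcn_dilations = c(1, 2),
    gru_hidden = 4, attn_heads = 1, dropout = 0, lr = 3e-3,
    batch_size = 32, epochs = 5, seed = seed, ...
  )
}

# Hand-built window_pairs with synthetic content (labels all `label` unless
# a vector is given).
fake_pairs <- function(n, omega = 10, channels = c("Ax", "Ay"), label = 1,
                       subject = "S001", age_group = "20-29", seed = 1) {
  set.seed(seed)
  X <- array(rnorm(n * omega * length(channels)),
             c(n, omega, length(channels)),
             dimnames = list(NULL, NULL, channels))
  structure(
    list(
      X = X,
      Y = rep_len(label, n),
      channels = channels,
      omega = as.integer(omega),
      fs_hz = 50,
      meta = list(subject_id = subject, age_group = age_group,
                  speed_condition = "normal", task = "STW"),
      source = tibble::tibble(subject_id = subject, age_group = age_group,
                              speed_condition = "normal", task = "STW",
                              start = seq_len(n))
    ),
    class = "window_pairs"
  )
}

# Step-by-step scalar Kalman recursion, written independently of the
# package implementation, as the machine-precision oracle.
kalman_oracle <- function(x, q, r) {
  out <- numeric(length(x))
  est <- x[1]
  P <- r
  out[1] <- est
  for (k in seq_along(x)[-1]) {
    P_pred <- P + q
    K <- P_pred / (P_pred + r)
    est <- est + K * (x[k] - est)
    P <- (1 - K) * P_pred
    out[k] <- est
  }
  out
}

# Brute-force transition scan: the reference implementation for event
# extraction, deliberately written as an explicit loop.
scan_events_oracle <- function(binary, fs_hz = 50, t0 = 0) {
  ev <- character(0)
  tt <- numeric(0)
  for (i in seq_along(binary)[-1]) {
    if (binary[i] == 1 && binary[i - 1] == 0) {
      ev <- c(ev, "HS"); tt <- c(tt, t0 + (i - 1) / fs_hz)
    } else if (binary[i] == 0 && binary[i - 1] == 1) {
      ev <- c(ev, "TO"); tt <- c(tt, t0 + (i - 1) / fs_hz)
    }
  }
  tibble::tibble(event = ev, time_s = tt)
}

# Least-squares amplitude of a pure tone, for filter attenuation checks.
tone_amplitude <- function(y, freq, t) {
  X <- cbind(sin(2 * pi * freq * t), cos(2 * pi * freq * t))
  cf <- qr.solve(X, y)
  sqrt(sum(cf^2))
}
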