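arch_names <- c("tcn_gru", "bitcn_bigru", "bitcn_bigru_crossattn")

test_that("every architecture maps any window batch into [0, 1]", {
  B <- 5; T <- 12; C <- 3
  set.seed(11)
  Xm <- matrix(rnorm(B * T * C), B * T, C)
  for (arch in arch_names) {
    cfg <- tiny_model_config(arch, seed = 2)
    params <- withr::with_seed(2, gaitevents:::init_params(cfg, C))
    fw <- gaitevents:::model_forward(params, cfg, Xm, B, T)
    expect_length(fw$p, B)
    expect_true(all(fw$p >= 0 & fw$p <= 1), label = arch)
  }
})

test_that("analytic gradients match finite differences for all architectures", {
  B <- 3; T <- 8; C <- 2
  for (arch in arch_names) {
    cfg <- tiny_model_config(arch, seed = 5)
    set.seed(5)
    params <- gaitevents:::init_params(cfg, C)
    # jitter away from exact ReLU kinks (zero biases + all-negative
    # receptive fields put some pre-activations exactly at zero, where the
    # two-sided difference quotient is not the subgradient backprop uses)
    params <- lapply(params, function(w) {
      jit <- rnorm(length(w), 0, 0.05)
      if (is.null(dim(w))) w + jit else w + array(jit, dim(w))
    })
    Xm <- matrix(rnorm(B * T * C), B * T, C)
    y <- c(1, 0, 1)
    loss_of <- function(p) {
      mean(abs(gaitevents:::model_forward(p, cfg, Xm, B, T)$p - y))
    }
    fw <- gaitevents:::model_forward(params, cfg, Xm, B, T)
    dp <- sign(fw$p - y) / B
    grads <- gaitevents:::model_backward(params, cfg, fw, dp, B, T)
    expect_setequal(names(grads), names(params))
    num_at <- function(nm, i, eps) {
      p_hi <- params; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- params; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      (loss_of(p_hi) - loss_of(p_lo)) / (2 * eps)
    }
    worst <- 0
    checked <- 0
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        n1 <- num_at(nm, i, 1e-5)
        n2 <- num_at(nm, i, 1e-6)
        # a step-size-dependent quotient marks a ReLU/|.| kink straddle,
        # where the difference quotient is not the derivative; skip those
        if (abs(n1 - n2) > 1e-3 * max(1e-8, abs(n1) + abs(n2))) next
        checked <- checked + 1
        ana <- grads[[nm]][i]
        worst <- max(worst, abs(n2 - ana) / max(1e-8, abs(n2) + abs(ana)))
      }
    }
    expect_gt(checked, 0.8 * length(params) * 2)
    expect_lt(worst, 1e-4)
  }
})

test_that("attention weights are a distribution over key positions", {
  cfg <- tiny_model_config("bitcn_bigru_crossattn", seed = 3)
  model <- build_model(cfg, in_channels = 2, omega = 12)
  set.seed(3)
  X <- array(rnorm(4 * 12 * 2), c(4, 12, 2))
  aw <- attention_weights(model, X)
  expect_length(aw, 4)
  for (w in aw) {
    for (head in w) {
      expect_equal(rowSums(head), rep(1, 12), tolerance = 1e-10)
      expect_true(all(head >= 0))
    }
  }
})

test_that("tied BiTCN branches are time-reversal images of each other", {
  cfg <- tiny_model_config("bitcn_bigru", seed = 9, tie_bitcn = TRUE)
  B <- 2; T <- 10; C <- 3
  set.seed(9)
  params <- gaitevents:::init_params(cfg, C)
  Xm <- matrix(rnorm(B * T * C), B * T, C)
  rev_idx <- gaitevents:::time_rev_idx(B, T)
  fw_x <- gaitevents:::model_forward(params, cfg, Xm, B, T)
  fw_rev <- gaitevents:::model_forward(params, cfg, Xm[rev_idx, ], B, T)
  # forward-branch features of the reversed window equal the (re-reversed)
  # backward-branch features of the original window
  expect_equal(fw_rev$cache$tf$out, fw_x$cache$tb$out, tolerance = 1e-12)
})

test_that("training drives a constant-label problem to confident predictions", {
  split <- list(train = fake_pairs(200, label = 1, seed = 21),
                val = fake_pairs(50, label = 1, seed = 22))
  cfg <- tiny_model_config("tcn_gru", seed = 1)
  model <- build_model(cfg, in_channels = 2, omega = 10)
  model <- train_gait_model(model, split, epochs = 50)
  expect_lt(dplyr::last(model$history$train_loss), 0.1)
  Xn <- gaitevents:::normalize_windows(split$train$X, model$channels,
                                       model$normalization)
  preds <- gaitevents:::predict_pairs(model, Xn)
  expect_true(all(preds > 0.9))
})

test_that("returned weights are the best validation checkpoint", {
  split <- list(train = fake_pairs(120, label = rep(c(0, 1), 60), seed = 31),
                val = fake_pairs(40, label = rep(c(0, 1), 20), seed = 32))
  cfg <- tiny_model_config("tcn_gru", seed = 2)
  model <- build_model(cfg, in_channels = 2, omega = 10)
  model <- train_gait_model(model, split, epochs = 6)
  h <- model$history
  expect_equal(nrow(h), 6)
  expect_equal(model$best_epoch, which.min(h$val_loss))
  # the stored weights reproduce the best epoch's validation loss, which by
  # construction is <= the final epoch's validation loss
  Xn <- gaitevents:::normalize_windows(split$val$X, model$channels,
                                       model$normalization)
  revalidated <- mean(abs(gaitevents:::predict_pairs(model, Xn) - split$val$Y))
  expect_equal(revalidated, min(h$val_loss), tolerance = 1e-12)
  expect_lte(revalidated, dplyr::last(h$val_loss))
})

test_that("training is deterministic under the config seed", {
  split <- list(train = fake_pairs(100, label = rep(c(0, 1), 50), seed = 41),
                val = fake_pairs(30, label = rep(c(0, 1), 15), seed = 42))
  run_once <- function() {
    cfg <- tiny_model_config("tcn_gru", seed = 77)
    m <- build_model(cfg, in_channels = 2, omega = 10)
    train_gait_model(m, split, epochs = 3)
  }
  m1 <- run_once()
  m2 <- run_once()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("a scaled synthetic cohort trains to a low validation MAE", {
  res <- run_gait_experiment(
    n_subjects = 10, epochs = 5, architecture = "tcn_gru",
    age_groups = "(all)", seed = 3
  )
  expect_lt(min(res$model$history$val_loss), 0.25)
})

test_that("predict_trace aligns to samples omega+1..n and stays in [0,1]", {
  rec <- preprocess_recording(simulate_recording(gait_profile(seed = 6)))
  n <- nrow(rec$signals)
  tr <- predict_trace(oracle_model(40), rec)
  expect_equal(nrow(tr), n - 40)
  expect_equal(tr$sample, 41:n)
  # perfect-model composition: the trace is exactly the stance reference
  expect_equal(tr$stance_prob, as.numeric(rec$signals$stance[41:n]))
  expect_true(all(tr$stance_prob >= 0 & tr$stance_prob <= 1))
  shorty <- rec
  shorty$signals <- shorty$signals[1:40, ]
  expect_error(predict_trace(oracle_model(40), shorty), "shorter")
})

test_that("model configuration validates its arguments", {
  expect_error(model_config(epochs = 0), "epochs")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(gru_hidden = 10, attn_heads = 3), "divide")
})
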