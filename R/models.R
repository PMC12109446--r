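#' Sequence-model configuration
#'
#' Hyperparameters for the three window-to-stance-probability architectures.
#' All three share a temporal-convolution front end and a recurrent stage:
#'
#' * `tcn_gru` — causal dilated-convolution residual stack, then a
#'   unidirectional GRU; the final hidden state feeds a sigmoid head.
#' * `bitcn_bigru` — a forward TCN stack plus a second stack applied to the
#'   time-reversed window (features concatenated), then a bidirectional GRU;
#'   both final states feed the head.
#' * `bitcn_bigru_crossattn` — additionally applies multi-head scaled
#'   dot-product cross-attention with queries from the BiGRU sequence output
#'   and keys/values from the BiTCN sequence output, mean-pools the attended
#'   sequence over time, and applies the sigmoid head.
#'
#' @param architecture One of `"tcn_gru"`, `"bitcn_bigru"`,
#'   `"bitcn_bigru_crossattn"`.
#' @param tcn_channels Channels per TCN block.
#' @param tcn_kernel Convolution kernel size.
#' @param tcn_dilations Integer dilation per residual block.
#' @param gru_hidden GRU hidden size (per direction).
#' @param attn_heads Attention heads; must divide `2 * gru_hidden`.
#' @param dropout Dropout fraction inside TCN blocks, `0 <= dropout < 1`.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (default 50).
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param attn_reverse If `TRUE`, swap the cross-attention wiring (queries
#'   from the BiTCN stream, keys/values from the BiGRU stream).
#' @param tie_bitcn If `TRUE` the forward and backward TCN stacks share
#'   weights (used to expose the time-reversal symmetry of the branches).
#' @return A `model_config` list.
#' @export
model_config <- function(architecture = c("bitcn_bigru_crossattn",
                                          "tcn_gru", "bitcn_bigru"),
                         tcn_channels = 64,
                         tcn_kernel = 3,
                         tcn_dilations = c(1, 2, 4),
                         gru_hidden = 64,
                         attn_heads = 4,
                         dropout = 0.2,
                         lr = 1e-3,
                         batch_size = 64,
                         epochs = 50,
                         seed = 1,
                         attn_reverse = FALSE,
                         tie_bitcn = FALSE) {
  architecture <- match.arg(architecture)
  for (nm in c("tcn_channels", "tcn_kernel", "gru_hidden", "attn_heads",
               "batch_size", "epochs")) {
    v <- get(nm)
    stop_if_not_scalar_number(v, nm, positive = TRUE)
    if (v != round(v)) abort(sprintf("`%s` must be an integer.", nm))
  }
  if (epochs < 1) abort("`epochs` must be >= 1.")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  stop_if_not_scalar_number(lr, "lr", positive = TRUE)
  if ((2 * gru_hidden) %% attn_heads != 0) {
    abort("`attn_heads` must divide 2 * gru_hidden (the attention width).")
  }
  structure(
    list(
      architecture = architecture,
      tcn_channels = as.integer(tcn_channels),
      tcn_kernel = as.integer(tcn_kernel),
      tcn_dilations = as.integer(tcn_dilations),
      gru_hidden = as.integer(gru_hidden),
      attn_heads = as.integer(attn_heads),
      dropout = dropout,
      lr = lr,
      batch_size = as.integer(batch_size),
      epochs = as.integer(epochs),
      seed = as.integer(seed),
      attn_reverse = isTRUE(attn_reverse),
      tie_bitcn = isTRUE(tie_bitcn)
    ),
    class = "model_config"
  )
}

# Initialize the flat named parameter list for an architecture.
init_params <- function(cfg, in_channels) {
  k <- cfg$tcn_kernel
  ch <- cfg$tcn_channels
  H <- cfg$gru_hidden
  p <- list()
  add_tcn <- function(p, pf, cin) {
    for (i in seq_along(cfg$tcn_dilations)) {
      bp <- sprintf("%s.b%d", pf, i)
      p[[paste0(bp, ".c1.W")]] <- glorot(c(k, cin, ch))
      p[[paste0(bp, ".c1.b")]] <- numeric(ch)
      p[[paste0(bp, ".c2.W")]] <- glorot(c(k, ch, ch))
      p[[paste0(bp, ".c2.b")]] <- numeric(ch)
      if (cin != ch) p[[paste0(bp, ".res.W")]] <- glorot(c(cin, ch))
      cin <- ch
    }
    p
  }
  add_gru <- function(p, pf, cin) {
    p[[paste0(pf, ".Wx")]] <- glorot(c(cin, 3L * H))
    p[[paste0(pf, ".U")]] <- glorot(c(H, 3L * H))
    p[[paste0(pf, ".bx")]] <- numeric(3L * H)
    p[[paste0(pf, ".bh")]] <- numeric(3L * H)
    p
  }
  if (cfg$architecture == "tcn_gru") {
    p <- add_tcn(p, "tcn", in_channels)
    p <- add_gru(p, "gru", ch)
    p[["head.W"]] <- glorot(c(H, 1L))
    p[["head.b"]] <- 0
  } else {
    p <- add_tcn(p, "tcnf", in_channels)
    if (!cfg$tie_bitcn) p <- add_tcn(p, "tcnb", in_channels)
    p <- add_gru(p, "gruf", 2L * ch)
    p <- add_gru(p, "grub", 2L * ch)
    if (cfg$architecture == "bitcn_bigru") {
      p[["head.W"]] <- glorot(c(2L * H, 1L))
      p[["head.b"]] <- 0
    } else {
      D <- 2L * H
      q_in <- if (cfg$attn_reverse) 2L * ch else 2L * H
      kv_in <- if (cfg$attn_reverse) 2L * H else 2L * ch
      p[["attn.Wq"]] <- glorot(c(q_in, D))
      p[["attn.bq"]] <- numeric(D)
      p[["attn.Wk"]] <- glorot(c(kv_in, D))
      p[["attn.bk"]] <- numeric(D)
      p[["attn.Wv"]] <- glorot(c(kv_in, D))
      p[["attn.bv"]] <- numeric(D)
      p[["attn.Wo"]] <- glorot(c(D, D))
      p[["attn.bo"]] <- numeric(D)
      p[["head.W"]] <- glorot(c(D, 1L))
      p[["head.b"]] <- 0
    }
  }
  p
}

#' Build an (untrained) gait model
#'
#' Instantiates the architecture described by a [model_config()] with
#' seeded random weights. The model predicts, for each sliding window, the
#' probability that the sample immediately following the window is in stance.
#'
#' @param cfg A [model_config()].
#' @param in_channels Number of input channels (6 after default
#'   preprocessing).
#' @param omega Window length the model operates on.
#' @return A `gait_model` object.
#' @export
build_model <- function(cfg, in_channels = 6, omega = 40) {
  if (!inherits(cfg, "model_config")) abort("`cfg` must be a `model_config`.")
  stop_if_not_scalar_number(in_channels, "in_channels", positive = TRUE)
  stop_if_not_scalar_number(omega, "omega", positive = TRUE)
  params <- with_local_seed(cfg$seed, init_params(cfg, as.integer(in_channels)))
  structure(
    list(
      cfg = cfg,
      params = params,
      in_channels = as.integer(in_channels),
      omega = as.integer(omega),
      channels = NULL,
      normalization = NULL,
      history = NULL,
      best_epoch = NA_integer_,
      trained = FALSE
    ),
    class = "gait_model"
  )
}

#' @export
print.gait_model <- function(x, ...) {
  np <- sum(purrr::map_int(x$params, length))
  cat(sprintf(
    "<gait_model> %s | omega = %d | %d input channels | %d parameters | %s\n",
    x$cfg$architecture, x$omega, x$in_channels, np,
    if (x$trained) sprintf("trained (best epoch %d)", x$best_epoch) else "untrained"
  ))
  invisible(x)
}

# Full forward pass. Xm is (B*T) x C in time-major layout.
# Returns p (length B), caches for the backward pass, and (optionally)
# attention weights.
model_forward <- function(params, cfg, Xm, B, T, training = FALSE,
                          keep_attention = FALSE) {
  arch <- cfg$architecture
  ca <- list()
  if (arch == "tcn_gru") {
    tc <- tcn_fwd(params, "tcn", Xm, cfg$tcn_dilations, B, T, cfg$dropout, training)
    g <- gru_fwd(params, "gru", tc$out, B, T)
    hd <- head_fwd(params, g$h_last)
    ca <- list(tc = tc, g = g, hd = hd)
  } else {
    rev_idx <- time_rev_idx(B, T)
    pf_b <- if (cfg$tie_bitcn) "tcnf" else "tcnb"
    tf <- tcn_fwd(params, "tcnf", Xm, cfg$tcn_dilations, B, T, cfg$dropout, training)
    tb <- tcn_fwd(params, pf_b, Xm[rev_idx, , drop = FALSE], cfg$tcn_dilations,
                  B, T, cfg$dropout, training)
    Z <- cbind(tf$out, tb$out[rev_idx, , drop = FALSE])
    gf <- gru_fwd(params, "gruf", Z, B, T)
    gb <- gru_fwd(params, "grub", Z[rev_idx, , drop = FALSE], B, T)
    ca <- list(tf = tf, tb = tb, gf = gf, gb = gb, rev_idx = rev_idx, Z = Z)
    if (arch == "bitcn_bigru") {
      hin <- cbind(gf$h_last, gb$h_last)
      hd <- head_fwd(params, hin)
      ca$hd <- hd
    } else {
      S <- cbind(gf$Hseq, gb$Hseq[rev_idx, , drop = FALSE])
      if (cfg$attn_reverse) {
        at <- attn_fwd(params, Z, S, cfg$attn_heads, B, T)
      } else {
        at <- attn_fwd(params, S, Z, cfg$attn_heads, B, T)
      }
      P <- mean_pool_fwd(at$out, B, T)
      hd <- head_fwd(params, P)
      ca$S <- S
      ca$at <- at
      ca$hd <- hd
    }
  }
  out <- list(p = ca$hd$p, cache = ca)
  if (keep_attention && !is.null(ca$at)) out$attention <- ca$at$cache$A
  out
}

# Backward pass: dp is dLoss/dp (length B). Returns the named gradient list.
model_backward <- function(params, cfg, fw, dp, B, T) {
  gr <- new_grad_env()
  ca <- fw$cache
  arch <- cfg$architecture
  if (arch == "tcn_gru") {
    dh_last <- head_bwd(gr, params, dp, ca$hd$cache)
    dZ <- gru_bwd(gr, params, "gru", NULL, dh_last, ca$g$cache, B, T)
    tcn_bwd(gr, params, "tcn", dZ, ca$tc$caches, cfg$tcn_dilations, B, T)
  } else {
    rev_idx <- ca$rev_idx
    H <- cfg$gru_hidden
    ch2 <- 2L * cfg$tcn_channels
    if (arch == "bitcn_bigru") {
      dhin <- head_bwd(gr, params, dp, ca$hd$cache)
      dZ <- gru_bwd(gr, params, "gruf", NULL, dhin[, 1:H, drop = FALSE],
                    ca$gf$cache, B, T)
      dZr <- gru_bwd(gr, params, "grub", NULL,
                     dhin[, (H + 1L):(2L * H), drop = FALSE], ca$gb$cache, B, T)
      dZ <- dZ + dZr[rev_idx, , drop = FALSE]
    } else {
      dP <- head_bwd(gr, params, dp, ca$hd$cache)
      dO2 <- mean_pool_bwd(dP, B, T)
      ab <- attn_bwd(gr, params, dO2, ca$at$cache, B, T)
      if (cfg$attn_reverse) {
        dZ_attn <- ab$dS
        dS <- ab$dU2
      } else {
        dS <- ab$dS
        dZ_attn <- ab$dU2
      }
      dZ <- gru_bwd(gr, params, "gruf", dS[, 1:H, drop = FALSE], NULL,
                    ca$gf$cache, B, T)
      dSb <- dS[, (H + 1L):(2L * H), drop = FALSE][rev_idx, , drop = FALSE]
      dZr <- gru_bwd(gr, params, "grub", dSb, NULL, ca$gb$cache, B, T)
      dZ <- dZ + dZr[rev_idx, , drop = FALSE] + dZ_attn
    }
    pf_b <- if (cfg$tie_bitcn) "tcnf" else "tcnb"
    dXf <- tcn_bwd(gr, params, "tcnf", dZ[, 1:(ch2 / 2), drop = FALSE],
                   ca$tf$caches, cfg$tcn_dilations, B, T)
    dZb <- dZ[, (ch2 / 2 + 1L):ch2, drop = FALSE][rev_idx, , drop = FALSE]
    dXb <- tcn_bwd(gr, params, pf_b, dZb, ca$tb$caches, cfg$tcn_dilations, B, T)
    dXf + dXb[rev_idx, , drop = FALSE]
  }
  gr$g
}

# Convert rows `idx` of an (N, T, C) window array into the (B*T) x C
# time-major matrix layout (a plain column-major reshape).
batch_matrix <- function(X, idx) {
  nb <- length(idx)
  sub <- X[idx, , , drop = FALSE]
  matrix(sub, nrow = nb * dim(X)[2], ncol = dim(X)[3])
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  params
}

# Forward a full window set in batches (no dropout), returning probabilities.
predict_pairs <- function(model, X) {
  N <- dim(X)[1]
  T <- dim(X)[2]
  p <- numeric(N)
  bs <- model$cfg$batch_size
  at <- 1L
  while (at <= N) {
    idx <- at:min(at + bs - 1L, N)
    Xm <- batch_matrix(X, idx)
    fw <- model_forward(model$params, model$cfg, Xm, length(idx), T,
                        training = FALSE)
    p[idx] <- fw$p
    at <- at + bs
  }
  p
}

# Apply the model's stored normalization statistics to a window array.
normalize_windows <- function(X, channels, norm) {
  for (i in seq_along(channels)) {
    st <- norm[norm$channel == channels[i], ]
    X[, , i] <- (X[, , i] - st$mean) / st$sd
  }
  X
}

#' Train a gait model
#'
#' Minimizes the mean absolute error between the predicted stance
#' probability and the 0/1 stance label with Adam, for `cfg$epochs` epochs,
#' validating after every epoch and returning the weights with the lowest
#' validation MAE (ties keep the earlier epoch). Per-channel z-score
#' normalization statistics are computed from the training windows and
#' stored with the model, so inference reuses exactly the training scaling.
#' Training is deterministic given the config seed (initialization, batch
#' shuffling and dropout all draw from it).
#'
#' @param model A `gait_model` from [build_model()].
#' @param split A `dataset_split` with non-empty `train` and `val` sets.
#' @param epochs Optional override of `cfg$epochs`.
#' @param verbose Print one line per epoch.
#' @return The trained `gait_model` with `history` (tibble of per-epoch
#'   train/val loss), `best_epoch` and `normalization` filled in.
#' @export
train_gait_model <- function(model, split, epochs = NULL, verbose = FALSE) {
  if (!inherits(model, "gait_model")) abort("`model` must be a `gait_model`.")
  if (is.null(split$train) || is.null(split$val) ||
      length(split$train$Y) == 0 || length(split$val$Y) == 0) {
    abort("`split` must contain non-empty train and val sets.")
  }
  cfg <- model$cfg
  n_epochs <- as.integer(epochs %||% cfg$epochs)
  if (n_epochs < 1) abort("`epochs` must be >= 1.")
  tr <- split$train
  va <- split$val
  if (dim(tr$X)[3] != model$in_channels) {
    abort(sprintf("Model expects %d channels; training data has %d.",
                  model$in_channels, dim(tr$X)[3]))
  }
  T <- tr$omega
  if (T != model$omega) {
    abort(sprintf("Model expects omega = %d; data has omega = %d.",
                  model$omega, T))
  }

  # Train-set normalization, applied to every partition.
  norm <- purrr::map_dfr(seq_along(tr$channels), function(i) {
    x <- tr$X[, , i]
    tibble::tibble(channel = tr$channels[i], mean = mean(x),
                   sd = max(sd(x), 1e-12))
  })
  Xtr <- normalize_windows(tr$X, tr$channels, norm)
  Xva <- normalize_windows(va$X, va$channels, norm)
  ytr <- tr$Y
  yva <- va$Y
  N <- length(ytr)

  hist_rows <- vector("list", n_epochs)
  best <- list(val = Inf, params = NULL, epoch = NA_integer_)

  with_local_seed(cfg$seed, {
    params <- init_params(cfg, model$in_channels)
    state <- new.env(parent = emptyenv())
    state$t <- 0
    state$m <- list()
    state$v <- list()
    tmp_model <- model

    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(N)
      at <- 1L
      tot_loss <- 0
      n_batches <- 0L
      while (at <= N) {
        idx <- ord[at:min(at + cfg$batch_size - 1L, N)]
        B <- length(idx)
        Xm <- batch_matrix(Xtr, idx)
        fw <- model_forward(params, cfg, Xm, B, T, training = TRUE)
        resid <- fw$p - ytr[idx]
        tot_loss <- tot_loss + mean(abs(resid))
        dp <- sign(resid) / B
        grads <- model_backward(params, cfg, fw, dp, B, T)
        params <- adam_step(params, grads, state, cfg$lr)
        n_batches <- n_batches + 1L
        at <- at + cfg$batch_size
      }
      tmp_model$params <- params
      pv <- predict_pairs(tmp_model, Xva)
      val_loss <- mean(abs(pv - yva))
      hist_rows[[ep]] <- tibble::tibble(
        epoch = ep,
        train_loss = tot_loss / n_batches,
        val_loss = val_loss
      )
      if (val_loss < best$val) {
        best$val <- val_loss
        best$params <- params
        best$epoch <- ep
      }
      if (verbose) {
        message(sprintf("epoch %3d  train MAE %.4f  val MAE %.4f",
                        ep, tot_loss / n_batches, val_loss))
      }
    }
  })

  model$params <- best$params
  model$history <- dplyr::bind_rows(hist_rows)
  model$best_epoch <- best$epoch
  model$normalization <- norm
  model$channels <- tr$channels
  model$trained <- TRUE
  model
}

#' Predict a stance-probability trace over a recording
#'
#' Runs sliding-window inference over a preprocessed recording: window `t`
#' produces the stance probability for sample `t + omega`, so the trace is
#' aligned to samples `omega + 1 .. n` and the first `omega` samples have no
#' prediction. The model's stored train-set normalization is applied.
#'
#' @param model A trained `gait_model` (or [oracle_model()]).
#' @param rec A preprocessed `gait_recording` whose channels match the
#'   model's.
#' @param omega Optional override of the model's window length.
#' @return A tibble with columns `sample` (`omega + 1 .. n`), `time`, and
#'   `stance_prob` in `[0, 1]`.
#' @export
predict_trace <- function(model, rec, omega = NULL) {
  assert_recording(rec)
  omega <- as.integer(omega %||% model$omega)
  n <- nrow(rec$signals)
  if (n < omega + 1L) {
    abort(sprintf("Recording (%d samples) is shorter than omega + 1 = %d.",
                  n, omega + 1L))
  }
  if (inherits(model, "gait_oracle_model")) {
    if (!"stance" %in% names(rec$signals)) {
      abort("The oracle model needs the recording's `stance` reference.")
    }
    p <- as.numeric(rec$signals$stance[(omega + 1L):n])
  } else {
    if (!model$trained) abort("Model is untrained; call `train_gait_model()` first.")
    chans <- recording_channels(rec)
    if (!identical(chans, model$channels)) {
      abort(sprintf(
        "Recording channels (%s) do not match the model's (%s).",
        paste(chans, collapse = ","), paste(model$channels, collapse = ",")
      ))
    }
    M <- as.matrix(rec$signals[, chans])
    np <- n - omega
    X <- array(0, dim = c(np, omega, length(chans)))
    for (j in seq_len(omega)) X[, j, ] <- M[j:(j + np - 1L), , drop = FALSE]
    X <- normalize_windows(X, chans, model$normalization)
    p <- predict_pairs(model, X)
  }
  tibble::tibble(
    sample = (omega + 1L):n,
    time = rec$signals$time[(omega + 1L):n],
    stance_prob = p
  )
}

#' An oracle "model" that reads the stance reference
#'
#' Returns the true stance label as its prediction. Useful to validate the
#' event-extraction and scoring stages in isolation: with a perfect
#' predictor, every residual timing error comes from the 50 Hz label
#' quantization alone.
#'
#' @param omega Window length the oracle pretends to use.
#' @return A `gait_oracle_model` usable with [predict_trace()].
#' @export
oracle_model <- function(omega = 40) {
  structure(
    list(omega = as.integer(omega), trained = TRUE, in_channels = 0L,
         params = list(), best_epoch = NA_integer_,
         cfg = list(architecture = "oracle")),
    class = c("gait_oracle_model", "gait_model")
  )
}

#' @export
tidy.gait_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble::tibble(epoch = integer(), train_loss = double(),
                          val_loss = double()))
  }
  x$history
}

#' @export
glance.gait_model <- function(x, ...) {
  tibble::tibble(
    architecture = x$cfg$architecture,
    n_parameters = sum(purrr::map_int(x$params, length)),
    epochs_run = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_mae = if (is.null(x$history)) NA_real_ else min(x$history$val_loss),
    trained = x$trained
  )
}

#' Save / load a trained model checkpoint
#'
#' Serializes weights, config, normalization statistics and history into a
#' single file.
#'
#' @param model A `gait_model`.
#' @param path Checkpoint file path.
#' @export
save_gait_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_gait_model
#' @export
load_gait_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "gait_model")) abort("File does not contain a `gait_model`.")
  m
}

#' Inspect cross-attention weights on one batch of windows
#'
#' @param model A `gait_model` with the cross-attention architecture.
#' @param X A window array (`n x omega x channels`), already preprocessed.
#' @return A list (one per window) of per-head `omega x omega` attention
#'   matrices; each row (query) sums to 1.
#' @export
attention_weights <- function(model, X) {
  if (model$cfg$architecture != "bitcn_bigru_crossattn") {
    abort("Attention weights exist only for the cross-attention architecture.")
  }
  if (!is.null(model$normalization)) {
    X <- normalize_windows(X, model$channels, model$normalization)
  }
  B <- dim(X)[1]
  T <- dim(X)[2]
  Xm <- batch_matrix(X, seq_len(B))
  fw <- model_forward(model$params, model$cfg, Xm, B, T, training = FALSE,
                      keep_attention = TRUE)
  fw$attention
}
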