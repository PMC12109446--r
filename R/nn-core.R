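# Internal neural-network primitives.
#
# All sequence tensors are stored as (B*T) x C matrices in time-major row
# order: row (t-1)*B + b holds batch element b at time step t. This makes a
# causal dilated convolution a sum of row-shifted matrix products and keeps
# every learnable operation a plain BLAS call. Each *_fwd returns the output
# plus the cache its *_bwd needs; gradients are accumulated into an
# environment keyed by parameter name, mirroring the flat parameter list.

sigmoid <- function(x) 1 / (1 + exp(-x))

rows_at <- function(t, B) ((t - 1L) * B + 1L):(t * B)

# Row permutation that reverses the time axis; an involution.
time_rev_idx <- function(B, T) {
  rep((T:1) - 1L, each = B) * B + rep(seq_len(B), T)
}

add_bias <- function(Y, b) {
  # Broadcast a length-C bias over the rows of a (B*T) x C matrix.
  Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
}

glorot <- function(dims) {
  if (length(dims) == 3) {
    # conv kernel (k, Cin, Cout)
    fan_in <- dims[1] * dims[2]
    fan_out <- dims[1] * dims[3]
  } else {
    fan_in <- dims[1]
    fan_out <- dims[2]
  }
  s <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -s, s), dim = dims)
}

new_grad_env <- function() {
  e <- new.env(parent = emptyenv())
  e$g <- list()
  e
}

grad_add <- function(gr, name, value) {
  if (is.null(gr$g[[name]])) {
    gr$g[[name]] <- value
  } else {
    gr$g[[name]] <- gr$g[[name]] + value
  }
  invisible(NULL)
}

## ---- causal dilated convolution ------------------------------------------

conv_fwd <- function(Xm, W, b, dil, B, T) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  Y <- matrix(b, B * T, Cout, byrow = TRUE)
  for (j in seq_len(k)) {
    s <- (j - 1L) * dil
    if (s < T) {
      Wj <- matrix(W[j, , ], Cin, Cout)
      Y[(s * B + 1L):(T * B), ] <- Y[(s * B + 1L):(T * B), , drop = FALSE] +
        Xm[1L:((T - s) * B), , drop = FALSE] %*% Wj
    }
  }
  Y
}

conv_bwd <- function(dY, Xm, W, dil, B, T) {
  k <- dim(W)[1]; Cin <- dim(W)[2]; Cout <- dim(W)[3]
  dW <- array(0, dim = dim(W))
  dX <- matrix(0, B * T, Cin)
  for (j in seq_len(k)) {
    s <- (j - 1L) * dil
    if (s < T) {
      ro <- (s * B + 1L):(T * B)
      ri <- 1L:((T - s) * B)
      dW[j, , ] <- crossprod(Xm[ri, , drop = FALSE], dY[ro, , drop = FALSE])
      dX[ri, ] <- dX[ri, , drop = FALSE] +
        dY[ro, , drop = FALSE] %*% t(matrix(W[j, , ], Cin, Cout))
    }
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

## ---- TCN residual block ---------------------------------------------------

# Two causal convolutions with ReLU and (inverted) dropout, plus an identity
# or 1x1-projected residual, ReLU after the addition.
tcn_block_fwd <- function(params, pf, Xm, dil, B, T, dropout, training) {
  W1 <- params[[paste0(pf, ".c1.W")]]; b1 <- params[[paste0(pf, ".c1.b")]]
  W2 <- params[[paste0(pf, ".c2.W")]]; b2 <- params[[paste0(pf, ".c2.b")]]
  h1 <- conv_fwd(Xm, W1, b1, dil, B, T)
  m1 <- h1 > 0
  a1 <- h1 * m1
  d1mask <- NULL
  if (training && dropout > 0) {
    d1mask <- matrix(
      (runif(length(a1)) >= dropout) / (1 - dropout), nrow(a1), ncol(a1)
    )
    a1 <- a1 * d1mask
  }
  h2 <- conv_fwd(a1, W2, b2, dil, B, T)
  m2 <- h2 > 0
  a2 <- h2 * m2
  d2mask <- NULL
  if (training && dropout > 0) {
    d2mask <- matrix(
      (runif(length(a2)) >= dropout) / (1 - dropout), nrow(a2), ncol(a2)
    )
    a2 <- a2 * d2mask
  }
  rname <- paste0(pf, ".res.W")
  if (!is.null(params[[rname]])) {
    res <- Xm %*% params[[rname]]
  } else {
    res <- Xm
  }
  pre <- a2 + res
  mo <- pre > 0
  out <- pre * mo
  list(
    out = out,
    cache = list(
      Xm = Xm, a1 = a1, m1 = m1, m2 = m2, mo = mo,
      d1mask = d1mask, d2mask = d2mask, dil = dil
    )
  )
}

tcn_block_bwd <- function(gr, params, pf, dOut, cache, B, T) {
  W1 <- params[[paste0(pf, ".c1.W")]]
  W2 <- params[[paste0(pf, ".c2.W")]]
  dil <- cache$dil
  dpre <- dOut * cache$mo
  # residual path
  rname <- paste0(pf, ".res.W")
  if (!is.null(params[[rname]])) {
    grad_add(gr, rname, crossprod(cache$Xm, dpre))
    dX <- dpre %*% t(params[[rname]])
  } else {
    dX <- dpre
  }
  # conv path
  da2 <- dpre
  if (!is.null(cache$d2mask)) da2 <- da2 * cache$d2mask
  dh2 <- da2 * cache$m2
  g2 <- conv_bwd(dh2, cache$a1, W2, dil, B, T)
  grad_add(gr, paste0(pf, ".c2.W"), g2$dW)
  grad_add(gr, paste0(pf, ".c2.b"), g2$db)
  da1 <- g2$dX
  if (!is.null(cache$d1mask)) da1 <- da1 * cache$d1mask
  dh1 <- da1 * cache$m1
  g1 <- conv_bwd(dh1, cache$Xm, W1, dil, B, T)
  grad_add(gr, paste0(pf, ".c1.W"), g1$dW)
  grad_add(gr, paste0(pf, ".c1.b"), g1$db)
  dX + g1$dX
}

tcn_fwd <- function(params, pf, Xm, dilations, B, T, dropout, training) {
  caches <- vector("list", length(dilations))
  h <- Xm
  for (i in seq_along(dilations)) {
    blk <- tcn_block_fwd(params, sprintf("%s.b%d", pf, i), h, dilations[i],
                         B, T, dropout, training)
    h <- blk$out
    caches[[i]] <- blk$cache
  }
  list(out = h, caches = caches)
}

tcn_bwd <- function(gr, params, pf, dOut, caches, dilations, B, T) {
  d <- dOut
  for (i in rev(seq_along(dilations))) {
    d <- tcn_block_bwd(gr, params, sprintf("%s.b%d", pf, i), d, caches[[i]], B, T)
  }
  d
}

## ---- GRU ------------------------------------------------------------------

# Gates follow the usual convention:
#   r_t = sigmoid(W_r x_t + U_r h_{t-1} + b)
#   z_t = sigmoid(W_z x_t + U_z h_{t-1} + b)
#   n_t = tanh(W_n x_t + r_t * (U_n h_{t-1} + b))
#   h_t = (1 - z_t) * n_t + z_t * h_{t-1}
gru_fwd <- function(params, pf, Xm, B, T) {
  Wx <- params[[paste0(pf, ".Wx")]]
  U <- params[[paste0(pf, ".U")]]
  bx <- params[[paste0(pf, ".bx")]]
  bh <- params[[paste0(pf, ".bh")]]
  H <- ncol(U) / 3L
  i1 <- 1L:H; i2 <- (H + 1L):(2L * H); i3 <- (2L * H + 1L):(3L * H)
  XW <- add_bias(Xm %*% Wx, bx)
  h <- matrix(0, B, H)
  Hseq <- matrix(0, B * T, H)
  steps <- vector("list", T)
  for (t in seq_len(T)) {
    ro <- rows_at(t, B)
    Hh <- add_bias(h %*% U, bh)
    r <- sigmoid(XW[ro, i1, drop = FALSE] + Hh[, i1, drop = FALSE])
    z <- sigmoid(XW[ro, i2, drop = FALSE] + Hh[, i2, drop = FALSE])
    Hh3 <- Hh[, i3, drop = FALSE]
    n <- tanh(XW[ro, i3, drop = FALSE] + r * Hh3)
    hn <- (1 - z) * n + z * h
    steps[[t]] <- list(r = r, z = z, n = n, hprev = h, Hh3 = Hh3)
    h <- hn
    Hseq[ro, ] <- h
  }
  list(Hseq = Hseq, h_last = h,
       cache = list(Xm = Xm, XW = XW, steps = steps, H = H))
}

gru_bwd <- function(gr, params, pf, dHseq, dh_last, cache, B, T) {
  U <- params[[paste0(pf, ".U")]]
  Wx <- params[[paste0(pf, ".Wx")]]
  H <- cache$H
  dU <- matrix(0, H, 3L * H)
  dbh <- numeric(3L * H)
  dXW <- matrix(0, B * T, 3L * H)
  dh <- if (is.null(dh_last)) matrix(0, B, H) else dh_last
  for (t in rev(seq_len(T))) {
    ro <- rows_at(t, B)
    if (!is.null(dHseq)) dh <- dh + dHseq[ro, , drop = FALSE]
    st <- cache$steps[[t]]
    dz <- dh * (st$hprev - st$n)
    dn <- dh * (1 - st$z)
    dhprev <- dh * st$z
    dan <- dn * (1 - st$n^2)
    dr <- dan * st$Hh3
    dar <- dr * st$r * (1 - st$r)
    daz <- dz * st$z * (1 - st$z)
    dHh <- cbind(dar, daz, dan * st$r)
    dXW[ro, ] <- cbind(dar, daz, dan)
    dhprev <- dhprev + dHh %*% t(U)
    dU <- dU + crossprod(st$hprev, dHh)
    dbh <- dbh + colSums(dHh)
    dh <- dhprev
  }
  grad_add(gr, paste0(pf, ".U"), dU)
  grad_add(gr, paste0(pf, ".bh"), dbh)
  grad_add(gr, paste0(pf, ".Wx"), crossprod(cache$Xm, dXW))
  grad_add(gr, paste0(pf, ".bx"), colSums(dXW))
  dXW %*% t(Wx)
}

## ---- multi-head scaled-dot-product cross-attention ------------------------

# Queries come from S, keys/values from U2; softmax over the key time axis.
attn_fwd <- function(params, S, U2, n_heads, B, T) {
  Q <- add_bias(S %*% params[["attn.Wq"]], params[["attn.bq"]])
  K <- add_bias(U2 %*% params[["attn.Wk"]], params[["attn.bk"]])
  V <- add_bias(U2 %*% params[["attn.Wv"]], params[["attn.bv"]])
  D <- ncol(Q)
  dh <- D %/% n_heads
  O <- matrix(0, B * T, D)
  A_store <- vector("list", B)
  bidx <- lapply(seq_len(B), function(b) b + B * (0:(T - 1L)))
  for (b in seq_len(B)) {
    rb <- bidx[[b]]
    Ab <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      Sc <- Q[rb, cols, drop = FALSE] %*% t(K[rb, cols, drop = FALSE]) / sqrt(dh)
      Sc <- Sc - apply(Sc, 1, max)
      A <- exp(Sc)
      A <- A / rowSums(A)
      O[rb, cols] <- A %*% V[rb, cols, drop = FALSE]
      Ab[[h]] <- A
    }
    A_store[[b]] <- Ab
  }
  O2 <- add_bias(O %*% params[["attn.Wo"]], params[["attn.bo"]])
  list(out = O2,
       cache = list(S = S, U2 = U2, Q = Q, K = K, V = V, O = O,
                    A = A_store, bidx = bidx, n_heads = n_heads, dh = dh))
}

attn_bwd <- function(gr, params, dO2, cache, B, T) {
  grad_add(gr, "attn.Wo", crossprod(cache$O, dO2))
  grad_add(gr, "attn.bo", colSums(dO2))
  dO <- dO2 %*% t(params[["attn.Wo"]])
  Q <- cache$Q; K <- cache$K; V <- cache$V
  dQ <- matrix(0, nrow(Q), ncol(Q))
  dK <- matrix(0, nrow(K), ncol(K))
  dV <- matrix(0, nrow(V), ncol(V))
  dh <- cache$dh
  for (b in seq_len(B)) {
    rb <- cache$bidx[[b]]
    for (h in seq_len(cache$n_heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$A[[b]][[h]]
      dOb <- dO[rb, cols, drop = FALSE]
      Vb <- V[rb, cols, drop = FALSE]
      dA <- dOb %*% t(Vb)
      dV[rb, cols] <- dV[rb, cols, drop = FALSE] + crossprod(A, dOb)
      dSc <- A * (dA - rowSums(dA * A))
      dQ[rb, cols] <- dQ[rb, cols, drop = FALSE] +
        dSc %*% K[rb, cols, drop = FALSE] / sqrt(dh)
      dK[rb, cols] <- dK[rb, cols, drop = FALSE] +
        crossprod(dSc, Q[rb, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  grad_add(gr, "attn.Wq", crossprod(cache$S, dQ))
  grad_add(gr, "attn.bq", colSums(dQ))
  grad_add(gr, "attn.Wk", crossprod(cache$U2, dK))
  grad_add(gr, "attn.bk", colSums(dK))
  grad_add(gr, "attn.Wv", crossprod(cache$U2, dV))
  grad_add(gr, "attn.bv", colSums(dV))
  list(dS = dQ %*% t(params[["attn.Wq"]]),
       dU2 = dK %*% t(params[["attn.Wk"]]) + dV %*% t(params[["attn.Wv"]]))
}

## ---- pooling and head ------------------------------------------------------

mean_pool_fwd <- function(Xm, B, T) {
  P <- matrix(0, B, ncol(Xm))
  for (t in seq_len(T)) P <- P + Xm[rows_at(t, B), , drop = FALSE]
  P / T
}

mean_pool_bwd <- function(dP, B, T) {
  dX <- matrix(0, B * T, ncol(dP))
  dPT <- dP / T
  for (t in seq_len(T)) dX[rows_at(t, B), ] <- dPT
  dX
}

head_fwd <- function(params, Hm) {
  z <- as.vector(Hm %*% params[["head.W"]]) + params[["head.b"]]
  p <- sigmoid(z)
  list(p = p, cache = list(Hm = Hm, p = p))
}

head_bwd <- function(gr, params, dp, cache) {
  dz <- dp * cache$p * (1 - cache$p)
  grad_add(gr, "head.W", crossprod(cache$Hm, matrix(dz, ncol = 1)))
  grad_add(gr, "head.b", sum(dz))
  matrix(dz, ncol = 1) %*% t(params[["head.W"]])
}
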