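# Self-contained neural-network layers with manual backpropagation, written
# against base matrix ops (BLAS-backed). Sequences are batched as 3D arrays
# A[b, t, d] with a validity mask; padded positions are excluded from the
# loss and frozen through the recurrence. All parameter containers are flat
# named lists of numeric arrays so the Adam update is a single generic walk.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Glorot-uniform initializer, seeded by the caller's RNG state.
glorot <- function(nin, nout, dims = c(nin, nout)) {
  r <- sqrt(6 / (nin + nout))
  array(runif(prod(dims), -r, r), dim = dims)
}

# Flatten A[b, t, d] -> (B*T) x D matrix (first two dims collapse,
# column-major, so row index runs over b fastest).
flat_bt <- function(A) {
  d <- dim(A)
  matrix(A, d[1] * d[2], d[3])
}

unflat_bt <- function(M, B, T) {
  array(M, dim = c(B, T, ncol(M)))
}

# ---- 1-D convolution over the sequence axis -------------------------------
# out[, t, ] = sum_o Xpad[, t + o - 1, ] %*% W[o, , ] + b, with zero padding
# of (w-1)/2 positions per side so the output keeps length T. Computed as w
# shifted matrix products; the unfolded design matrix is never materialized.

conv1d_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1]; T <- d[2]; D <- d[3]
  w <- dim(W)[1]; Fn <- dim(W)[3]
  pad <- (w - 1L) %/% 2L
  Xp <- array(0, dim = c(B, T + 2L * pad, D))
  Xp[, pad + seq_len(T), ] <- X
  out <- matrix(rep(b, each = B * T), B * T, Fn)
  for (o in seq_len(w)) {
    out <- out + flat_bt(Xp[, o:(o + T - 1L), , drop = FALSE]) %*% W[o, , ]
  }
  list(out = unflat_bt(out, B, T), Xp = Xp)
}

conv1d_backward <- function(dOut, cache, W) {
  Xp <- cache$Xp
  d <- dim(dOut); B <- d[1]; T <- d[2]
  w <- dim(W)[1]; D <- dim(W)[2]
  pad <- (w - 1L) %/% 2L
  dM <- flat_bt(dOut)
  dW <- array(0, dim = dim(W))
  dXp <- array(0, dim = dim(Xp))
  for (o in seq_len(w)) {
    idx <- o:(o + T - 1L)
    Xo <- flat_bt(Xp[, idx, , drop = FALSE])
    dW[o, , ] <- crossprod(Xo, dM)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] +
      unflat_bt(dM %*% t(W[o, , ]), B, T)
  }
  list(dX = dXp[, pad + seq_len(T), , drop = FALSE],
       dW = dW, db = colSums(dM))
}

# ---- LSTM -----------------------------------------------------------------
# Single direction; set reverse = TRUE to scan right-to-left (used for the
# second half of the bidirectional layer). Gate order i, f, g, o. The mask
# freezes h and c at padded steps so right-padding never leaks into the
# states seen by real positions (in either scan direction).

lstm_forward <- function(X, mask, Wx, Wh, b, reverse = FALSE) {
  d <- dim(X); B <- d[1]; T <- d[2]
  H <- ncol(Wh)
  stopifnot(H %% 4L == 0L)
  H <- H %/% 4L
  ts <- if (reverse) rev(seq_len(T)) else seq_len(T)
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  out <- array(0, dim = c(B, T, H))
  cache <- vector("list", T)
  for (k in seq_len(T)) {
    t <- ts[k]
    Xt <- matrix(X[, t, ], B)
    m <- mask[, t]
    z <- Xt %*% Wx + h %*% Wh
    z <- sweep(z, 2L, b, "+")
    ig <- sigmoid(z[, 1:H, drop = FALSE])
    fg <- sigmoid(z[, H + 1:H, drop = FALSE])
    gg <- tanh(z[, 2L * H + 1:H, drop = FALSE])
    og <- sigmoid(z[, 3L * H + 1:H, drop = FALSE])
    c_new <- fg * c + ig * gg
    tc <- tanh(c_new)
    h_new <- og * tc
    cache[[k]] <- list(Xt = Xt, h_prev = h, c_prev = c, i = ig, f = fg,
                       g = gg, o = og, tc = tc, m = m)
    h <- m * h_new + (1 - m) * h
    c <- m * c_new + (1 - m) * c
    out[, t, ] <- h
  }
  list(out = out, cache = cache, ts = ts)
}

lstm_backward <- function(dOut, fwd, Wx, Wh) {
  ts <- fwd$ts
  T <- length(ts)
  H <- ncol(Wh) %/% 4L
  B <- dim(dOut)[1]
  dWx <- array(0, dim = dim(Wx)); dWh <- array(0, dim = dim(Wh))
  db <- numeric(4L * H)
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  dX <- array(0, dim = c(B, T, nrow(Wx)))
  for (k in rev(seq_len(T))) {
    t <- ts[k]
    cc <- fwd$cache[[k]]
    dh <- dh + matrix(dOut[, t, ], B)
    m <- cc$m
    dh_eff <- m * dh
    dc_eff <- m * dc
    do_ <- dh_eff * cc$tc
    dcn <- dc_eff + dh_eff * cc$o * (1 - cc$tc^2)
    di <- dcn * cc$g
    df <- dcn * cc$c_prev
    dg <- dcn * cc$i
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$Xt, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dX[, t, ] <- dz %*% t(Wx)
    dh <- dz %*% t(Wh) + (1 - m) * dh
    dc <- dcn * cc$f + (1 - m) * dc
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- dense / activations / loss -------------------------------------------

dense_forward <- function(M, W, b) sweep(M %*% W, 2L, b, "+")

dense_backward <- function(dOut, M, W) {
  list(dM = dOut %*% t(W), dW = crossprod(M, dOut), db = colSums(dOut))
}

relu <- function(x) x * (x > 0)

# Row-normalized output activation. "sigmoid_norm" squashes each logit with
# a sigmoid then renormalizes the row to sum to 1; "softmax" is the usual
# alternative. Both return strictly positive rows summing to 1.
out_activation_forward <- function(Z, kind) {
  if (kind == "softmax") {
    E <- exp(Z - apply(Z, 1L, max))
    list(Y = E / rowSums(E), S = NULL)
  } else {
    S <- sigmoid(Z)
    list(Y = S / rowSums(S), S = S)
  }
}

out_activation_backward <- function(dY, Y, act, kind) {
  inner <- rowSums(dY * Y)
  if (kind == "softmax") {
    Y * (dY - inner)
  } else {
    S <- act$S
    (dY - inner) / rowSums(S) * S * (1 - S)
  }
}

# Kullback-Leibler divergence KL(target || output) summed over rows and
# divided by n_valid; for one-hot targets this is the mean negative log of
# the probability assigned to the true label. Returns the gradient wrt Y.
kl_loss <- function(Y, Tgt, valid) {
  eps <- 1e-12
  P <- pmax(Tgt, 0)
  lr <- rowSums(ifelse(P > 0, P * (log(pmax(P, eps)) - log(pmax(Y, eps))), 0))
  n <- sum(valid)
  loss <- sum(lr[valid]) / n
  dY <- matrix(0, nrow(Y), ncol(Y))
  dY[valid, ] <- -P[valid, , drop = FALSE] / pmax(Y[valid, , drop = FALSE], eps) / n
  list(loss = loss, dY = dY)
}

# ---- dropout ---------------------------------------------------------------
# Inverted dropout: scale kept units by 1/(1-rate) at train time so
# inference needs no rescaling.

dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array((runif(prod(dims)) >= rate) / (1 - rate), dim = dims)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
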