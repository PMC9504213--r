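# Minimal neural-network primitives for the convolutional-recurrent encoder:
# temporal (valid, stride-1) 1-D convolution, LSTM with backprop through time,
# and an Adam optimiser. Written against plain R matrix algebra; all shapes are
# small (windows of tens of timesteps, batches of tens of windows), so the
# per-timestep loop cost is negligible next to the matrix products.

# ---- 1-D temporal convolution ------------------------------------------------
# Input  X: n x C_in x T        (channels are input feature maps)
# Weight W: (C_in * k) x F      (column f = flattened kernel of filter f)
# Output:   n x F x (T - k + 1) after ReLU.

conv1d_forward <- function(X, W, b, activation = TRUE) {
  d <- dim(X); n <- d[1L]; C <- d[2L]; T <- d[3L]
  k <- nrow(W) / C
  T_out <- T - k + 1L
  if (T_out < 1L) stop("input too short for kernel", call. = FALSE)
  U <- matrix(0, n * T_out, C * k)
  for (j in seq_len(k)) {
    slab <- X[, , j:(j + T_out - 1L), drop = FALSE]        # n x C x T_out
    slab <- aperm(slab, c(1L, 3L, 2L))                     # n x T_out x C
    dim(slab) <- c(n * T_out, C)                           # row = (t-major, i-fast)
    U[, ((j - 1L) * C + 1L):(j * C)] <- slab
  }
  Z <- U %*% W + matrix(b, n * T_out, length(b), byrow = TRUE)
  A <- if (activation) pmax(Z, 0) else Z
  out <- A
  dim(out) <- c(n, T_out, ncol(W))
  out <- aperm(out, c(1L, 3L, 2L))                          # n x F x T_out
  list(out = out, cache = list(U = U, Z = Z, dims = c(n, C, T, k, T_out),
                               activation = activation))
}

conv1d_backward <- function(dOut, W, cache) {
  dm <- cache$dims
  n <- dm[1L]; C <- dm[2L]; T <- dm[3L]; k <- dm[4L]; T_out <- dm[5L]
  dA <- aperm(dOut, c(1L, 3L, 2L))                          # n x T_out x F
  dim(dA) <- c(n * T_out, ncol(W))
  dZ <- if (cache$activation) dA * (cache$Z > 0) else dA
  dW <- crossprod(cache$U, dZ)
  db <- colSums(dZ)
  dU <- tcrossprod(dZ, W)                                   # (n*T_out) x (C*k)
  dX <- array(0, dim = c(n, C, T))
  for (j in seq_len(k)) {
    blk <- dU[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    dim(blk) <- c(n, T_out, C)
    dX[, , j:(j + T_out - 1L)] <- dX[, , j:(j + T_out - 1L), drop = FALSE] +
      aperm(blk, c(1L, 3L, 2L))
  }
  list(dX = dX, dW = dW, db = db)
}

# ---- LSTM layer --------------------------------------------------------------
# Gate order in the stacked weight matrices: input, forget, cell, output.
# Wx: in_sz x 4H, Wh: H x 4H, b: 4H. Initial hidden/cell state are zero.

lstm_forward <- function(X, Wx, Wh, b) {
  d <- dim(X); n <- d[1L]; T <- d[3L]
  H <- ncol(Wh) / 4L
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  Hseq <- array(0, dim = c(n, H, T))
  steps <- vector("list", T)
  bmat <- matrix(b, n, 4L * H, byrow = TRUE)
  for (t in seq_len(T)) {
    xt <- matrix(X[, , t], n, d[2L])
    G <- xt %*% Wx + h %*% Wh + bmat
    i <- sigmoid(G[, 1:H, drop = FALSE])
    f <- sigmoid(G[, (H + 1L):(2L * H), drop = FALSE])
    g <- tanh(G[, (2L * H + 1L):(3L * H), drop = FALSE])
    o <- sigmoid(G[, (3L * H + 1L):(4L * H), drop = FALSE])
    c_prev <- cc; h_prev <- h
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    Hseq[, , t] <- h
    steps[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, tc = tc,
                       c_prev = c_prev, h_prev = h_prev, xt = xt)
  }
  list(Hseq = Hseq, h_final = h, cache = steps)
}

# dHseq: n x H x T gradient on the full hidden sequence (zeros where unused).
lstm_backward <- function(dHseq, X, Wx, Wh, cache) {
  d <- dim(X); n <- d[1L]; T <- d[3L]
  H <- ncol(Wh) / 4L
  dWx <- matrix(0, nrow(Wx), 4L * H)
  dWh <- matrix(0, H, 4L * H)
  db <- numeric(4L * H)
  dX <- array(0, dim = d)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  for (t in rev(seq_len(T))) {
    s <- cache[[t]]
    dh <- matrix(dHseq[, , t], n, H) + dh_next
    do_ <- dh * s$tc
    dc <- dc_next + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    df <- dc * s$c_prev
    dg <- dc * s$i
    dc_next <- dc * s$f
    dA <- cbind(di * s$i * (1 - s$i),
                df * s$f * (1 - s$f),
                dg * (1 - s$g^2),
                do_ * s$o * (1 - s$o))
    dWx <- dWx + crossprod(s$xt, dA)
    dWh <- dWh + crossprod(s$h_prev, dA)
    db <- db + colSums(dA)
    dX[, , t] <- tcrossprod(dA, Wx)
    dh_next <- tcrossprod(dA, Wh)
  }
  list(dX = dX, dWx = dWx, dWh = dWh, db = db)
}

# ---- Adam --------------------------------------------------------------------
# Parameters and gradients are nested lists of numeric arrays with identical
# structure; moment estimates are kept alongside in the encoder state.

adam_init <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

adam_step <- function(params, grads, m, v, t, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, m1, v1) {
    m1 <- beta1 * m1 + (1 - beta1) * g
    v1 <- beta2 * v1 + (1 - beta2) * g^2
    mhat <- m1 / (1 - beta1^t)
    vhat <- v1 / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m1, v = v1)
  }
  out_p <- params; out_m <- m; out_v <- v
  for (grp in names(params)) {
    for (l in seq_along(params[[grp]])) {
      for (nm in names(params[[grp]][[l]])) {
        r <- walk(params[[grp]][[l]][[nm]], grads[[grp]][[l]][[nm]],
                  m[[grp]][[l]][[nm]], v[[grp]][[l]][[nm]])
        out_p[[grp]][[l]][[nm]] <- r$p
        out_m[[grp]][[l]][[nm]] <- r$m
        out_v[[grp]][[l]][[nm]] <- r$v
      }
    }
  }
  list(params = out_p, m = out_m, v = out_v)
}
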