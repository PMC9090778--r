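# Neural-network primitives for the 1D U-Net.
#
# Tensors are dense arrays with layout (channels, time, batch); with that
# layout a (C, T, B) array flattens to a C x (T*B) matrix without copying,
# so per-channel operations (batch norm, bias, softmax) are plain row
# operations and convolutions reduce to one BLAS GEMM over an im2col
# matrix. Every `*_fwd` returns the output plus the cache its `*_bwd`
# needs; backward passes return the input gradient and parameter gradients.
# All gradients are exact (verified against central finite differences in
# the test suite).

conv_fwd <- function(X, p) {
  .conv1d_fwd(X, p$W, p$b, p$k, p$d)
}

conv_bwd <- function(dY, X, p) {
  .conv1d_bwd(dY, X, p$W, p$k, p$d)
}

# Pure-R reference implementations of the compiled convolution kernels;
# kept as the independent oracle the compiled path is tested against.
conv_fwd_ref <- function(X, p) {
  dm <- dim(X); C <- dm[1]; Tt <- dm[2]; B <- dm[3]
  k <- p$k; d <- p$d
  ext <- (k - 1) * d
  padl <- ext %/% 2
  Xp <- array(0, c(C, Tt + ext, B))
  Xp[, padl + seq_len(Tt), ] <- X
  M <- matrix(0, k * C, Tt * B)
  for (j in seq_len(k))
    M[((j - 1) * C + 1):(j * C), ] <- Xp[, seq_len(Tt) + (j - 1) * d, ]
  Y <- p$W %*% M + p$b
  dim(Y) <- c(nrow(p$W), Tt, B)
  Y
}

conv_bwd_ref <- function(dY, X, p) {
  dm <- dim(X); C <- dm[1]; Tt <- dm[2]; B <- dm[3]
  k <- p$k; d <- p$d
  ext <- (k - 1) * d
  padl <- ext %/% 2
  Xp <- array(0, c(C, Tt + ext, B))
  Xp[, padl + seq_len(Tt), ] <- X
  M <- matrix(0, k * C, Tt * B)
  for (j in seq_len(k))
    M[((j - 1) * C + 1):(j * C), ] <- Xp[, seq_len(Tt) + (j - 1) * d, ]
  Cout <- nrow(p$W)
  dYm <- matrix(dY, Cout, Tt * B)
  dW <- tcrossprod(dYm, M)
  db <- rowSums(dYm)
  dM <- crossprod(p$W, dYm)
  dXp <- array(0, c(C, Tt + ext, B))
  for (j in seq_len(k)) {
    idx <- seq_len(Tt) + (j - 1) * d
    dXp[, idx, ] <- array(dXp[, idx, ], c(C, Tt, B)) +
      array(dM[((j - 1) * C + 1):(j * C), ], c(C, Tt, B))
  }
  dX <- dXp[, padl + seq_len(Tt), , drop = FALSE]
  dim(dX) <- c(C, Tt, B)
  list(dX = dX, dW = dW, db = db)
}

relu_fwd <- function(X) {
  Y <- X
  Y[Y < 0] <- 0
  Y
}

relu_bwd <- function(dY, Y) {
  dX <- dY
  dX[Y <= 0] <- 0
  dX
}

bn_fwd <- function(X, p, buf, training, momentum = 0.1, eps = 1e-5) {
  dm <- dim(X); C <- dm[1]; N <- dm[2] * dm[3]
  Xm <- matrix(X, C, N)
  if (training) {
    mu <- rowMeans(Xm)
    v <- rowMeans(Xm * Xm) - mu * mu
    v[v < 0] <- 0
    buf$mean <- (1 - momentum) * buf$mean + momentum * mu
    buf$var <- (1 - momentum) * buf$var + momentum * v
  } else {
    mu <- buf$mean
    v <- buf$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (Xm - mu) * invstd
  Y <- p$gamma * xhat + p$beta
  dim(Y) <- dm
  list(Y = Y, buf = buf, cache = list(xhat = xhat, invstd = invstd,
                                      dims = dm, training = training))
}

bn_bwd <- function(dY, cache, p) {
  dm <- cache$dims; C <- dm[1]; N <- dm[2] * dm[3]
  dYm <- matrix(dY, C, N)
  xhat <- cache$xhat
  dgamma <- rowSums(dYm * xhat)
  dbeta <- rowSums(dYm)
  dxhat <- dYm * p$gamma
  if (cache$training) {
    dX <- cache$invstd *
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    dX <- cache$invstd * dxhat          # running stats are constants
  }
  dim(dX) <- dm
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

maxpool_fwd <- function(X, w) {
  dm <- dim(X); C <- dm[1]; Tt <- dm[2]; B <- dm[3]
  if (Tt %% w != 0)
    stop_spindlr("pooling width ", w, " does not divide length ", Tt)
  T2 <- Tt %/% w
  Xr <- X
  dim(Xr) <- c(C, w, T2, B)
  Y <- array(Xr[, 1, , ], c(C, T2, B))
  arg <- array(1L, c(C, T2, B))
  for (j in seq_len(w)[-1]) {
    cand <- array(Xr[, j, , ], c(C, T2, B))
    upd <- cand > Y
    Y[upd] <- cand[upd]
    arg[upd] <- j
  }
  list(Y = Y, arg = arg)
}

maxpool_bwd <- function(dY, arg, w) {
  dm <- dim(dY); C <- dm[1]; T2 <- dm[2]; B <- dm[3]
  dXr <- array(0, c(C, w, T2, B))
  for (j in seq_len(w)) {
    tmp <- dY
    tmp[arg != j] <- 0
    dXr[, j, , ] <- tmp
  }
  dim(dXr) <- c(C, w * T2, B)
  dXr
}

upsample_fwd <- function(X, w) {
  Tt <- dim(X)[2]
  Y <- X[, rep(seq_len(Tt), each = w), , drop = FALSE]
  Y
}

upsample_bwd <- function(dY, w) {
  dm <- dim(dY); C <- dm[1]; Tt <- dm[2] %/% w; B <- dm[3]
  dYr <- dY
  dim(dYr) <- c(C, w, Tt, B)
  dX <- array(0, c(C, Tt, B))
  for (j in seq_len(w)) dX <- dX + array(dYr[, j, , ], c(C, Tt, B))
  dX
}

concat_fwd <- function(A, B2) {
  da <- dim(A); db <- dim(B2)
  Y <- array(0, c(da[1] + db[1], da[2], da[3]))
  Y[seq_len(da[1]), , ] <- A
  Y[da[1] + seq_len(db[1]), , ] <- B2
  Y
}

concat_bwd <- function(dY, ca) {
  dm <- dim(dY)
  dA <- dY[seq_len(ca), , , drop = FALSE]
  dB <- dY[ca + seq_len(dm[1] - ca), , , drop = FALSE]
  dim(dA) <- c(ca, dm[2], dm[3])
  dim(dB) <- c(dm[1] - ca, dm[2], dm[3])
  list(dA = dA, dB = dB)
}

softmax2_fwd <- function(Z) {
  dm <- dim(Z)
  Zm <- matrix(Z, 2, dm[2] * dm[3])
  mx <- pmax(Zm[1, ], Zm[2, ])
  e1 <- exp(Zm[1, ] - mx); e2 <- exp(Zm[2, ] - mx)
  s <- e1 + e2
  P <- rbind(e1 / s, e2 / s)
  dim(P) <- dm
  P
}

softmax2_bwd <- function(dP, P) {
  dm <- dim(P)
  Pm <- matrix(P, 2, dm[2] * dm[3])
  dPm <- matrix(dP, 2, dm[2] * dm[3])
  inner <- colSums(Pm * dPm)
  dZ <- Pm * (dPm - rbind(inner, inner))
  dim(dZ) <- dm
  dZ
}

# Generalized dice loss over a 2-class batch.
# p, r: (2, T, B) arrays (predicted probabilities / one-hot targets).
# Class weights w_l = 1 / (sum_n r_ln)^2 with an epsilon floor guarding
# batches from which a class is absent.
gdice_fwd <- function(p, r, eps = 1e-8) {
  Pm <- matrix(p, 2); Rm <- matrix(r, 2)
  rs <- rowSums(Rm)
  w <- 1 / pmax(rs * rs, eps)
  num <- sum(w * rowSums(Rm * Pm))
  den <- sum(w * (rs + rowSums(Pm)))
  list(loss = 1 - 2 * num / den, w = w, num = num, den = den)
}

gdice_bwd <- function(p, r, fw) {
  dm <- dim(p)
  Rm <- matrix(r, 2)
  dP <- -2 * (fw$w * Rm * fw$den - fw$num * fw$w) / fw$den^2
  dim(dP) <- dm
  dP
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  st <- lapply(params, function(p) {
    lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
           function(x) list(m = x * 0, v = x * 0))
  })
  list(t = 0L, st = st)
}

adam_step <- function(params, grads, state, lr = 0.005, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (slot in names(grads[[nm]])) {
      g <- grads[[nm]][[slot]]
      s <- state$st[[nm]][[slot]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
      state$st[[nm]][[slot]] <- s
    }
  }
  list(params = params, state = state)
}
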