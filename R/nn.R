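# Neural network primitives: batched forward/backward passes written as
# matrix operations. Feature tensors of shape (batch B, positions L,
# channels C) are stored as (B*L) x C matrices with row index b + (l-1)*B,
# so array(H, c(B, L, C)) recovers the 3D view (column-major).

nn_glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

# ---- embedding ----------------------------------------------------------

embed_fwd <- function(E, tok, xl) {
  # tok, xl: (B, L) matrices; returns H (B*L, d+1) with xl flag channel
  B <- nrow(tok); L <- ncol(tok)
  ids <- as.vector(tok)                 # row order b + (l-1)*B
  H <- matrix(0, B * L, ncol(E) + 1L)
  nz <- ids > 0L
  H[nz, seq_len(ncol(E))] <- E[ids[nz], , drop = FALSE]
  H[, ncol(E) + 1L] <- as.vector(xl)
  list(H = H, ids = ids, d = ncol(E))
}

embed_bwd <- function(cache, dH, V) {
  ids <- cache$ids
  nz <- ids > 0L
  dE <- matrix(0, V, cache$d)
  if (any(nz)) {
    acc <- rowsum(dH[nz, seq_len(cache$d), drop = FALSE], group = ids[nz])
    dE[as.integer(rownames(acc)), ] <- acc
  }
  dE
}

# ---- 1D convolution (same padding) --------------------------------------

# Row-index vectors for the k shifted views of a (B, L) position grid;
# index B*L + 1 points at an all-zero padding row.
conv_shift_idx <- function(B, L, k) {
  p <- (k - 1L) %/% 2L
  zero_row <- B * L + 1L
  lapply(seq_len(k), function(t) {
    ls <- seq_len(L) + (t - p - 1L)
    idx <- rep((ls - 1L) * B, each = B) + rep(seq_len(B), L)
    idx[rep(ls < 1L | ls > L, each = B)] <- zero_row
    idx
  })
}

conv_fwd <- function(H, W, b, B, L) {
  C <- ncol(H)
  k <- as.integer(nrow(W) / C)
  idx <- conv_shift_idx(B, L, k)
  Hz <- rbind(H, 0)
  X <- matrix(0, B * L, k * C)
  for (t in seq_len(k))
    X[, ((t - 1L) * C + 1L):(t * C)] <- Hz[idx[[t]], , drop = FALSE]
  Z <- X %*% W
  Z <- sweep(Z, 2L, b, `+`)
  list(Z = Z, X = X, k = k, Cin = C, idx = idx)
}

conv_bwd <- function(cache, dZ, W, B, L) {
  k <- cache$k; C <- cache$Cin
  dW <- crossprod(cache$X, dZ)
  db <- colSums(dZ)
  dX <- dZ %*% t(W)
  # scatter-accumulate the k shifted gradient blocks back onto positions
  big <- matrix(0, k * B * L, C)
  for (t in seq_len(k))
    big[(t - 1L) * B * L + seq_len(B * L), ] <-
      dX[, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
  groups <- unlist(cache$idx)
  acc <- rowsum(big, group = groups)
  rn <- as.integer(rownames(acc))
  keep <- rn <= B * L
  dH <- matrix(0, B * L, C)
  dH[rn[keep], ] <- acc[keep, , drop = FALSE]
  list(dH = dH, dW = dW, db = db)
}

# ---- layer norm over channels -------------------------------------------

LN_EPS <- 1e-5

ln_fwd <- function(Z, g, b) {
  mu <- rowMeans(Z)
  xc <- Z - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  Y <- sweep(xhat, 2L, g, `*`)
  Y <- sweep(Y, 2L, b, `+`)
  list(Y = Y, xhat = xhat, inv = inv)
}

ln_bwd <- function(cache, dY, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dZ <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dZ = dZ, dg = dg, db = db)
}

# ---- local pooling along positions (window 2, stride 2) -----------------

pool_fwd <- function(H, mask, B, L, type) {
  C <- ncol(H)
  if (L %% 2L == 1L) {  # pad one masked position
    H <- rbind(H, matrix(0, B, C))
    mask <- cbind(mask, matrix(0L, B, 1L))
    L <- L + 1L
  }
  L2 <- L %/% 2L
  A <- array(H, c(B, L, C))
  m1 <- mask[, seq(1L, L, 2L), drop = FALSE]   # (B, L2)
  m2 <- mask[, seq(2L, L, 2L), drop = FALSE]
  H1 <- matrix(A[, seq(1L, L, 2L), ], B * L2, C)
  H2 <- matrix(A[, seq(2L, L, 2L), ], B * L2, C)
  v1 <- as.vector(m1); v2 <- as.vector(m2)
  newmask <- matrix(as.integer(v1 | v2), B, L2)
  if (type == "max") {
    X1 <- H1; X1[v1 == 0L, ] <- -Inf
    X2 <- H2; X2[v2 == 0L, ] <- -Inf
    take2 <- X2 > X1
    P <- X1
    P[take2] <- X2[take2]
    P[as.vector(newmask) == 0L, ] <- 0
    list(P = P, mask = newmask, take2 = take2, L2 = L2, Lpad = L)
  } else {
    cnt <- pmax(v1 + v2, 1L)
    P <- (H1 * v1 + H2 * v2) / cnt
    P[as.vector(newmask) == 0L, ] <- 0
    list(P = P, mask = newmask, cnt = cnt, v1 = v1, v2 = v2,
         L2 = L2, Lpad = L)
  }
}

pool_bwd <- function(cache, dP, B, L, type) {
  C <- ncol(dP)
  L2 <- cache$L2; Lpad <- cache$Lpad
  valid <- as.vector(cache$mask) == 1L
  dP[!valid, ] <- 0
  if (type == "max") {
    d1 <- dP * !cache$take2
    d2 <- dP * cache$take2
  } else {
    d1 <- dP * (cache$v1 / cache$cnt)
    d2 <- dP * (cache$v2 / cache$cnt)
  }
  dA <- array(0, c(B, Lpad, C))
  dA[, seq(1L, Lpad, 2L), ] <- array(d1, c(B, L2, C))
  dA[, seq(2L, Lpad, 2L), ] <- array(d2, c(B, L2, C))
  matrix(dA[, seq_len(L), ], B * L, C)
}

# ---- single-head cross-attention ----------------------------------------
# Each side's positions attend to the other side's positions; the
# projection matrices are shared between the two directions (one parameter
# set, consistent with the shared-encoder design). Vectorized over the
# batch; loops run only over the (short, pooled) position axes.

# One attention direction: queries Qm (B*Lq, a) over keys/values Km, Vm
# (B*Lk, a), with key validity mask_k and query validity mask_q (B x L).
attn_one_dir <- function(Qm, Km, Vm, mask_q, mask_k, B, Lq, Lk, sc) {
  a <- ncol(Qm)
  repq <- rep(seq_len(B), Lq)           # batch id of each query row
  S <- array(0, c(B, Lq, Lk))
  for (j in seq_len(Lk)) {
    Kj <- Km[B * (j - 1L) + seq_len(B), , drop = FALSE]
    S[, , j] <- matrix(rowSums(Qm * Kj[repq, , drop = FALSE]), B, Lq) * sc
    S[mask_k[, j] == 0L, , j] <- -Inf
  }
  mx <- matrix(-Inf, B, Lq)
  for (j in seq_len(Lk)) mx <- pmax(mx, S[, , j])
  A <- array(0, c(B, Lq, Lk))
  rs <- matrix(0, B, Lq)
  for (j in seq_len(Lk)) {
    E <- exp(S[, , j] - mx)
    E[!is.finite(E)] <- 0
    A[, , j] <- E
    rs <- rs + E
  }
  rs[rs == 0] <- 1
  Cm <- matrix(0, B * Lq, a)
  for (j in seq_len(Lk)) {
    A[, , j] <- (A[, , j] / rs) * mask_q   # zero attention of padded queries
    Vj <- Vm[B * (j - 1L) + seq_len(B), , drop = FALSE]
    Cm <- Cm + as.vector(A[, , j]) * Vj[repq, , drop = FALSE]
  }
  list(C = Cm, A = A)
}

attn_fwd <- function(Ha, Hb, mask_a, mask_b, Wq, Wk, Wv, B, La, Lb) {
  a <- ncol(Wq)
  sc <- 1 / sqrt(a)
  Qa <- Ha %*% Wq; Ka <- Ha %*% Wk; Va <- Ha %*% Wv
  Qb <- Hb %*% Wq; Kb <- Hb %*% Wk; Vb <- Hb %*% Wv
  ab <- attn_one_dir(Qa, Kb, Vb, mask_a, mask_b, B, La, Lb, sc)
  ba <- attn_one_dir(Qb, Ka, Va, mask_b, mask_a, B, Lb, La, sc)
  list(Ca = ab$C, Cb = ba$C, Qa = Qa, Ka = Ka, Va = Va,
       Qb = Qb, Kb = Kb, Vb = Vb, Aab = ab$A, Aba = ba$A, sc = sc)
}

# Backward of one direction; returns gradients w.r.t. Q, K, V row matrices.
attn_one_dir_bwd <- function(dC, A, Qm, Km, Vm, B, Lq, Lk, sc) {
  a <- ncol(Qm)
  repq <- rep(seq_len(B), Lq)
  dA <- array(0, c(B, Lq, Lk))
  dV <- matrix(0, B * Lk, a)
  for (j in seq_len(Lk)) {
    Vj <- Vm[B * (j - 1L) + seq_len(B), , drop = FALSE]
    dA[, , j] <- matrix(rowSums(dC * Vj[repq, , drop = FALSE]), B, Lq)
    acc <- rowsum(as.vector(A[, , j]) * dC, group = repq)
    dV[B * (j - 1L) + seq_len(B), ] <- acc
  }
  s <- matrix(0, B, Lq)
  for (j in seq_len(Lk)) s <- s + dA[, , j] * A[, , j]
  dQ <- matrix(0, B * Lq, a)
  dK <- matrix(0, B * Lk, a)
  for (j in seq_len(Lk)) {
    dSj <- A[, , j] * (dA[, , j] - s)
    Kj <- Km[B * (j - 1L) + seq_len(B), , drop = FALSE]
    dQ <- dQ + (as.vector(dSj) * Kj[repq, , drop = FALSE]) * sc
    dK[B * (j - 1L) + seq_len(B), ] <-
      dK[B * (j - 1L) + seq_len(B), ] +
      rowsum(as.vector(dSj) * Qm, group = repq) * sc
  }
  list(dQ = dQ, dK = dK, dV = dV)
}

attn_bwd <- function(cache, dCa, dCb, Ha, Hb, mask_a, mask_b,
                     Wq, Wk, Wv, B, La, Lb) {
  g1 <- attn_one_dir_bwd(dCa, cache$Aab, cache$Qa, cache$Kb, cache$Vb,
                         B, La, Lb, cache$sc)
  g2 <- attn_one_dir_bwd(dCb, cache$Aba, cache$Qb, cache$Ka, cache$Va,
                         B, Lb, La, cache$sc)
  dQa <- g1$dQ; dKb <- g1$dK; dVb <- g1$dV
  dQb <- g2$dQ; dKa <- g2$dK; dVa <- g2$dV
  list(dHa = dQa %*% t(Wq) + dKa %*% t(Wk) + dVa %*% t(Wv),
       dHb = dQb %*% t(Wq) + dKb %*% t(Wk) + dVb %*% t(Wv),
       dWq = crossprod(Ha, dQa) + crossprod(Hb, dQb),
       dWk = crossprod(Ha, dKa) + crossprod(Hb, dKb),
       dWv = crossprod(Ha, dVa) + crossprod(Hb, dVb))
}

# ---- global pooling over positions --------------------------------------

gpool_fwd <- function(H, mask, B, L, type) {
  C <- ncol(H)
  if (type == "max") {
    G <- matrix(-Inf, B, C)
    amax <- matrix(1L, B, C)
    for (l in seq_len(L)) {
      Hl <- H[B * (l - 1L) + seq_len(B), , drop = FALSE]
      Hl[mask[, l] == 0L, ] <- -Inf
      upd <- Hl > G
      amax[upd] <- l
      G[upd] <- Hl[upd]
    }
    G[!is.finite(G)] <- 0
    list(G = G, amax = amax)
  } else {
    G <- matrix(0, B, C)
    for (l in seq_len(L)) {
      Hl <- H[B * (l - 1L) + seq_len(B), , drop = FALSE]
      G <- G + Hl * mask[, l]
    }
    cnt <- pmax(rowSums(mask), 1L)
    list(G = G / cnt, cnt = cnt)
  }
}

gpool_bwd <- function(cache, dG, mask, B, L, type) {
  C <- ncol(dG)
  dH <- matrix(0, B * L, C)
  if (type == "max") {
    for (l in seq_len(L)) {
      sel <- cache$amax == l
      dHl <- matrix(0, B, C)
      dHl[sel] <- dG[sel]
      dH[B * (l - 1L) + seq_len(B), ] <- dHl
    }
  } else {
    for (l in seq_len(L)) {
      dH[B * (l - 1L) + seq_len(B), ] <- dG * (mask[, l] / cache$cnt)
    }
  }
  dH
}
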