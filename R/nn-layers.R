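## Dense / normalization / attention / rotary-embedding primitives with
## hand-written backward passes. Every *Fwd returns list(y, cache); every
## *Bwd consumes the upstream gradient plus the cache and returns input and
## parameter gradients. Tensor convention: sequence tensors are [B, T, D]
## arrays; their matrix view has rows indexed (b, t) with b fastest, so
## row r = b + (t - 1) * B.

tensorToMat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

matToTensor <- function(m, B, T) {
  dim(m) <- c(B, T, ncol(m))
  m
}

sliceT <- function(x, t) {
  d <- dim(x)
  m <- x[, t, , drop = FALSE]
  dim(m) <- c(d[1], d[3])
  m
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- linear -----------------------------------------------------------------

linearFwd <- function(x, W, b) {
  y <- x %*% W
  # column-major bias broadcast, cheaper than sweep()
  y <- y + rep(b, each = nrow(y))
  list(y = y, cache = x)
}

linearBwd <- function(dy, W, cache) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))
}

## ---- layer normalization ----------------------------------------------------

layerNormFwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(xhat * 1, 2, g, "*")
  y <- sweep(y, 2, b, "+")
  list(y = y, cache = list(xhat = xhat, inv = inv))
}

layerNormBwd <- function(dy, g, cache) {
  xhat <- cache$xhat
  inv <- cache$inv
  D <- ncol(xhat)
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, "*")
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = dg, db = db)
}

## ---- relu + inverted dropout -------------------------------------------------

reluFwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
reluBwd <- function(dy, cache) dy * cache

dropoutFwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= p) / (1 - p)
  list(y = x * mask, cache = mask)
}

dropoutBwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## ---- learnable rotary position embedding ------------------------------------
## Pairs (2j-1, 2j) of the feature axis are rotated by angle pos * f_j with
## learnable log-frequencies (initialized to the standard 10000^(-2(j-1)/D)
## spectrum). Operates on the matrix view; `pos` gives the sequence position
## of each row.

ropeFwd <- function(x, logFreq, pos) {
  D <- ncol(x)
  half <- D / 2
  f <- exp(logFreq)                       # [half]
  ang <- outer(pos, f)                    # [N, half]
  co <- cos(ang); si <- sin(ang)
  odd <- seq(1, D, by = 2)
  even <- odd + 1
  x1 <- x[, odd, drop = FALSE]
  x2 <- x[, even, drop = FALSE]
  y <- x
  y[, odd] <- x1 * co - x2 * si
  y[, even] <- x1 * si + x2 * co
  list(y = y, cache = list(x1 = x1, x2 = x2, co = co, si = si,
                           ang = ang, pos = pos))
}

ropeBwd <- function(dy, logFreq, cache) {
  D <- ncol(dy)
  odd <- seq(1, D, by = 2)
  even <- odd + 1
  dy1 <- dy[, odd, drop = FALSE]
  dy2 <- dy[, even, drop = FALSE]
  co <- cache$co; si <- cache$si
  x1 <- cache$x1; x2 <- cache$x2
  dx <- dy
  dx[, odd] <- dy1 * co + dy2 * si
  dx[, even] <- -dy1 * si + dy2 * co
  # d(angle) then chain through angle = pos * exp(logFreq)
  dAng <- dy1 * (-x1 * si - x2 * co) + dy2 * (x1 * co - x2 * si)
  dLogFreq <- colSums(dAng * cache$ang)   # dang/dlogf = ang
  list(dx = dx, dLogFreq = dLogFreq)
}

## ---- multi-head scaled-dot-product attention --------------------------------
## q, k, v are [B, T, D] with D = heads * dh. Returns [B, Tq, D].

attentionFwd <- function(q, k, v, heads) {
  B <- dim(q)[1]; Tq <- dim(q)[2]; D <- dim(q)[3]
  Tk <- dim(k)[2]
  dh <- D / heads
  out <- array(0, c(B, Tq, D))
  probs <- vector("list", B)
  for (b in seq_len(B)) {
    Qb <- matrix(q[b, , ], Tq, D)
    Kb <- matrix(k[b, , ], Tk, D)
    Vb <- matrix(v[b, , ], Tk, D)
    Pb <- vector("list", heads)
    Ob <- matrix(0, Tq, D)
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      S <- Qb[, idx, drop = FALSE] %*% t(Kb[, idx, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1, max)
      P <- exp(S)
      P <- P / rowSums(P)
      Pb[[h]] <- P
      Ob[, idx] <- P %*% Vb[, idx, drop = FALSE]
    }
    probs[[b]] <- Pb
    out[b, , ] <- Ob
  }
  list(y = out, cache = list(q = q, k = k, v = v, probs = probs, heads = heads))
}

attentionBwd <- function(dy, cache) {
  q <- cache$q; k <- cache$k; v <- cache$v
  heads <- cache$heads
  B <- dim(q)[1]; Tq <- dim(q)[2]; D <- dim(q)[3]
  Tk <- dim(k)[2]
  dh <- D / heads
  dq <- array(0, dim(q)); dk <- array(0, dim(k)); dv <- array(0, dim(v))
  for (b in seq_len(B)) {
    Qb <- matrix(q[b, , ], Tq, D)
    Kb <- matrix(k[b, , ], Tk, D)
    Vb <- matrix(v[b, , ], Tk, D)
    dYb <- matrix(dy[b, , ], Tq, D)
    dQb <- matrix(0, Tq, D); dKb <- matrix(0, Tk, D); dVb <- matrix(0, Tk, D)
    for (h in seq_len(heads)) {
      idx <- ((h - 1) * dh + 1):(h * dh)
      P <- cache$probs[[b]][[h]]
      dO <- dYb[, idx, drop = FALSE]
      dVb[, idx] <- crossprod(P, dO)
      dP <- dO %*% t(Vb[, idx, drop = FALSE])
      dS <- P * (dP - rowSums(dP * P))
      dQb[, idx] <- dS %*% Kb[, idx, drop = FALSE] / sqrt(dh)
      dKb[, idx] <- crossprod(dS, Qb[, idx, drop = FALSE]) / sqrt(dh)
    }
    dq[b, , ] <- dQb; dk[b, , ] <- dKb; dv[b, , ] <- dVb
  }
  list(dq = dq, dk = dk, dv = dv)
}

## ---- token embedding with pad masking ---------------------------------------
## codes: [B, T] integers in 0..V (0 = pad, embeds to the zero vector).
## E: [V, D]. Returns the matrix view [B*T, D].

embeddingFwd <- function(codes, E) {
  idx <- as.vector(codes)
  if (any(idx < 0 | idx > nrow(E))) {
    stop(sprintf("condition code outside 0..%d", nrow(E)), call. = FALSE)
  }
  out <- matrix(0, length(idx), ncol(E))
  nz <- idx > 0
  out[nz, ] <- E[idx[nz], , drop = FALSE]
  list(y = out, cache = idx)
}

embeddingBwd <- function(dy, E, cache) {
  idx <- cache
  dE <- matrix(0, nrow(E), ncol(E))
  nz <- idx > 0
  if (any(nz)) {
    agg <- rowsum(dy[nz, , drop = FALSE], group = idx[nz])
    dE[as.integer(rownames(agg)), ] <- agg
  }
  dE
}
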