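## Multi-layer bidirectional LSTM stacks with hand-written backpropagation
## through time. Gate column blocks in the 4H-wide weight matrices are, in
## order: input (i), forget (f), candidate (g), output (o).
##
## For speed, sequence tensors are handled in their matrix view [B*T, D]
## (rows (b, t) with b fastest, so timestep t occupies the contiguous row
## block (t-1)*B + 1 .. t*B): the input-side products x W_x, the input
## gradients and all weight-gradient accumulations are single BLAS calls
## over the whole sequence; only the hidden-state recurrence h W_h runs in
## the timestep loop.
##
## State blocks follow the [layers x directions, B, H] convention: row
## (l - 1) * 2 + 1 is layer l forward, row (l - 1) * 2 + 2 is layer l
## backward (the stacks are always bidirectional).

lstmLayerFwd <- function(xm, B, T, Wx, Wh, b, h0, c0, reverse = FALSE) {
  out <- lstm_layer_fwd_cpp(xm, Wx, Wh, matrix(b, 1), h0, c0, B, T, reverse)
  list(y = out$y, hFinal = out$hFinal, cFinal = out$cFinal,
       cache = list(xm = xm, gates = out$gates, cAll = out$cAll,
                    cprevAll = out$cprevAll, hprevAll = out$hprevAll,
                    reverse = reverse, B = B, T = T))
}

lstmLayerBwd <- function(dym, dhFinal, dcFinal, Wx, Wh, cache) {
  out <- lstm_layer_bwd_cpp(dym, dhFinal, dcFinal, cache$xm, Wx, Wh,
                            cache$gates, cache$cAll, cache$cprevAll,
                            cache$hprevAll, cache$B, cache$T, cache$reverse)
  list(dx = out$dx, dWx = out$dWx, dWh = out$dWh, db = as.vector(out$db),
       dh0 = out$dh0, dc0 = out$dc0)
}

stateRow <- function(layer, direction) (layer - 1L) * 2L + direction

## params: list of layers, each list(fwd = list(Wx, Wh, b),
## bwd = list(Wx, Wh, b)). h0, c0: [2L, B, H]. Input/output in matrix view.

lstmStackFwd <- function(xm, B, T, params, h0, c0) {
  L <- length(params)
  H <- nrow(params[[1]]$fwd$Wh)
  caches <- vector("list", L)
  hFinal <- array(0, c(2 * L, B, H))
  cFinal <- array(0, c(2 * L, B, H))
  inp <- xm
  for (l in seq_len(L)) {
    rF <- stateRow(l, 1L); rB <- stateRow(l, 2L)
    fw <- lstmLayerFwd(inp, B, T, params[[l]]$fwd$Wx, params[[l]]$fwd$Wh,
                       params[[l]]$fwd$b, matrix(h0[rF, , ], B, H),
                       matrix(c0[rF, , ], B, H), reverse = FALSE)
    bw <- lstmLayerFwd(inp, B, T, params[[l]]$bwd$Wx, params[[l]]$bwd$Wh,
                       params[[l]]$bwd$b, matrix(h0[rB, , ], B, H),
                       matrix(c0[rB, , ], B, H), reverse = TRUE)
    hFinal[rF, , ] <- fw$hFinal; cFinal[rF, , ] <- fw$cFinal
    hFinal[rB, , ] <- bw$hFinal; cFinal[rB, , ] <- bw$cFinal
    caches[[l]] <- list(fw = fw$cache, bw = bw$cache)
    inp <- cbind(fw$y, bw$y)
  }
  list(y = inp, hFinal = hFinal, cFinal = cFinal, caches = caches)
}

lstmStackBwd <- function(dym, dhFinal, dcFinal, params, caches) {
  L <- length(params)
  H <- nrow(params[[1]]$fwd$Wh)
  B <- dim(dhFinal)[2]
  grads <- vector("list", L)
  dh0 <- array(0, dim(dhFinal))
  dc0 <- array(0, dim(dcFinal))
  dcur <- dym
  for (l in rev(seq_len(L))) {
    rF <- stateRow(l, 1L); rB <- stateRow(l, 2L)
    gF <- lstmLayerBwd(dcur[, 1:H, drop = FALSE],
                       matrix(dhFinal[rF, , ], B, H),
                       matrix(dcFinal[rF, , ], B, H),
                       params[[l]]$fwd$Wx, params[[l]]$fwd$Wh, caches[[l]]$fw)
    gB <- lstmLayerBwd(dcur[, (H + 1):(2 * H), drop = FALSE],
                       matrix(dhFinal[rB, , ], B, H),
                       matrix(dcFinal[rB, , ], B, H),
                       params[[l]]$bwd$Wx, params[[l]]$bwd$Wh, caches[[l]]$bw)
    grads[[l]] <- list(fwd = list(Wx = gF$dWx, Wh = gF$dWh, b = gF$db),
                       bwd = list(Wx = gB$dWx, Wh = gB$dWh, b = gB$db))
    dh0[rF, , ] <- gF$dh0; dc0[rF, , ] <- gF$dc0
    dh0[rB, , ] <- gB$dh0; dc0[rB, , ] <- gB$dc0
    dcur <- gF$dx + gB$dx
  }
  list(dx = dcur, grads = grads, dh0 = dh0, dc0 = dc0)
}
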