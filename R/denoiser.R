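## The sequence-to-sequence denoiser: a multi-layer bidirectional LSTM
## encoder over the noised sequence (initial cell states carry the noise
## level, initial hidden states are learnable), a transformer encoder over
## the condition embedding, a cross-attention fusion block (queries from the
## recurrent latent, keys/values from the condition features), and a
## bidirectional LSTM decoder seeded with the encoder's final states - a
## U-Net-style skip that hands shallow-layer summaries straight to the
## decoder - followed by a dense head predicting the clean sequence.

#' Denoiser architecture configuration
#'
#' Defaults mirror the full-scale architecture: padded length 250, condition
#' embedding width 256, 6 bidirectional LSTM layers of hidden width 512
#' (state blocks of leading dimension 12), 8 attention heads, 2 condition
#' transformer blocks, feed-forward width 1024. \code{tinyDenoiserConfig}
#' gives a desk-scale variant used throughout the test-suite and examples.
#'
#' @param seqLen padded sequence length.
#' @param condVocab secondary-structure vocabulary size (8; code 0 is pad).
#' @param condEmbedDim condition embedding width.
#' @param lstmHidden per-direction LSTM hidden width.
#' @param lstmLayers recurrent layers per stack.
#' @param attnHeads attention heads (must divide condEmbedDim).
#' @param transformerBlocks self-attention blocks over the condition.
#' @param ffDim transformer feed-forward width.
#' @param dropout transformer dropout probability (training only).
#' @param condDropoutProb per-position condition dropout probability used in
#'   training for classifier-free guidance.
#' @return A \code{\linkS4class{DenoiserConfig}}.
#' @examples
#' denoiserConfig()
#' tinyDenoiserConfig()
#' @export
denoiserConfig <- function(seqLen = 250L, condVocab = 8L, condEmbedDim = 256L,
                           lstmHidden = 512L, lstmLayers = 6L,
                           attnHeads = 8L, transformerBlocks = 2L,
                           ffDim = 1024L, dropout = 0.1,
                           condDropoutProb = 0.1) {
  new("DenoiserConfig", seqLen = as.integer(seqLen),
      condVocab = as.integer(condVocab),
      condEmbedDim = as.integer(condEmbedDim),
      lstmHidden = as.integer(lstmHidden), lstmLayers = as.integer(lstmLayers),
      bidirectional = TRUE, attnHeads = as.integer(attnHeads),
      transformerBlocks = as.integer(transformerBlocks),
      ffDim = as.integer(ffDim), dropout = dropout,
      condDropoutProb = condDropoutProb)
}

#' @rdname denoiserConfig
#' @export
tinyDenoiserConfig <- function(seqLen = 32L, condEmbedDim = 32L,
                               lstmHidden = 64L, lstmLayers = 2L,
                               attnHeads = 4L, transformerBlocks = 1L,
                               ffDim = 64L, dropout = 0,
                               condDropoutProb = 0.1) {
  denoiserConfig(seqLen = seqLen, condEmbedDim = condEmbedDim,
                 lstmHidden = lstmHidden, lstmLayers = lstmLayers,
                 attnHeads = attnHeads, transformerBlocks = transformerBlocks,
                 ffDim = ffDim, dropout = dropout,
                 condDropoutProb = condDropoutProb)
}

.uinit <- function(nr, nc, fanIn) {
  k <- 1 / sqrt(fanIn)
  matrix(runif(nr * nc, -k, k), nr, nc)
}

.lstmLayerParams <- function(din, H) {
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias starts open
  list(Wx = .uinit(din, 4 * H, H), Wh = .uinit(H, 4 * H, H), b = b)
}

.lstmStackParams <- function(dinFirst, H, L) {
  lapply(seq_len(L), function(l) {
    din <- if (l == 1) dinFirst else 2 * H
    list(fwd = .lstmLayerParams(din, H), bwd = .lstmLayerParams(din, H))
  })
}

.encoderBlockParams <- function(d, ff) {
  list(ln1 = list(g = rep(1, d), b = rep(0, d)),
       Wq = .uinit(d, d, d), bq = numeric(d),
       Wk = .uinit(d, d, d), bk = numeric(d),
       Wv = .uinit(d, d, d), bv = numeric(d),
       Wo = .uinit(d, d, d), bo = numeric(d),
       ln2 = list(g = rep(1, d), b = rep(0, d)),
       W1 = .uinit(d, ff, d), b1 = numeric(ff),
       W2 = .uinit(ff, d, ff), b2 = numeric(d))
}

.fusionParams <- function(d, H2, ff) {
  list(lnq = list(g = rep(1, H2), b = rep(0, H2)),
       Wq = .uinit(H2, d, H2), bq = numeric(d),
       Wk = .uinit(d, d, d), bk = numeric(d),
       Wv = .uinit(d, d, d), bv = numeric(d),
       Wo = .uinit(d, H2, d), bo = numeric(H2),
       lnf = list(g = rep(1, H2), b = rep(0, H2)),
       W1 = .uinit(H2, ff, H2), b1 = numeric(ff),
       W2 = .uinit(ff, H2, ff), b2 = numeric(H2))
}

#' Construct a denoiser with freshly initialized weights
#'
#' Weights are drawn uniformly at scale 1/sqrt(fan-in) (forget-gate biases
#' start at 1, layer norms at identity); the condition embedding table holds
#' condVocab + 1 rows, with the pad row pinned to zero so padding embeds to
#' the zero vector. Rotary log-frequencies start at the standard
#' \eqn{10000^{-2(j-1)/D}} spectrum and are trainable.
#'
#' @param config a \code{\linkS4class{DenoiserConfig}}.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param seed integer RNG seed for the initialization.
#' @return A \code{\linkS4class{PepDenoiser}} with every group trainable.
#' @examples
#' m <- newDenoiser(tinyDenoiserConfig(), cosineSchedule(8), seed = 1)
#' countParameters(m)
#' @export
newDenoiser <- function(config, schedule = cosineSchedule(64L), seed = 1L) {
  validObject(config)
  d <- config@condEmbedDim; H <- config@lstmHidden; L <- config@lstmLayers
  ff <- config@ffDim; V <- config@condVocab
  params <- withSeed(seed, {
    E <- matrix(rnorm((V + 1) * d, sd = 0.5), V + 1, d)
    E[1, ] <- 0  # pad row, pinned
    list(
      condEmbed = list(E = E),
      rope = list(logFreq = log(10000^(-2 * (seq_len(d / 2) - 1) / d))),
      condEncoder = lapply(seq_len(config@transformerBlocks),
                           function(i) .encoderBlockParams(d, ff)),
      encoderLSTM = .lstmStackParams(1L, H, L),
      h0 = array(rnorm(2 * L * H, sd = 0.01), c(2 * L, 1, H)),
      fusion = .fusionParams(d, 2 * H, ff),
      decoderLSTM = .lstmStackParams(2L * H, H, L),
      head = list(W = .uinit(2 * H, 1, 2 * H), b = 0)
    )
  })
  new("PepDenoiser", config = config, params = params, schedule = schedule,
      trainable = names(params))
}

#' Count trainable parameters
#'
#' \code{countParameters} enumerates the model's actual arrays;
#' \code{countParametersConfig} computes the same total analytically from an
#' architecture configuration. Both return the total with a per-component
#' breakdown attached as the \code{"breakdown"} attribute.
#'
#' @param x a \code{\linkS4class{PepDenoiser}} or, for the analytic variant,
#'   a \code{\linkS4class{DenoiserConfig}}.
#' @return Integer-valued total parameter count.
#' @export
countParameters <- function(x) {
  stopifnot(is(x, "PepDenoiser"))
  breakdown <- vapply(x@params, paramCount, numeric(1))
  structure(sum(breakdown), breakdown = breakdown)
}

#' @rdname countParameters
#' @param config a \code{\linkS4class{DenoiserConfig}}.
#' @export
countParametersConfig <- function(config) {
  d <- config@condEmbedDim; H <- config@lstmHidden; L <- config@lstmLayers
  ff <- config@ffDim; V <- config@condVocab
  lstmLayer <- function(din) 2 * (4 * H * (din + H + 1))
  encStack <- lstmLayer(1) + (L - 1) * lstmLayer(2 * H)
  decStack <- L * lstmLayer(2 * H)
  block <- 2 * 2 * d + 4 * (d * d + d) + d * ff + ff + ff * d + d
  H2 <- 2 * H
  fusion <- 2 * H2 + (H2 * d + d) + 2 * (d * d + d) + (d * H2 + H2) +
    2 * H2 + (H2 * ff + ff) + (ff * H2 + H2)
  breakdown <- c(condEmbed = (V + 1) * d, rope = d / 2,
                 condEncoder = config@transformerBlocks * block,
                 encoderLSTM = encStack, h0 = 2 * L * H, fusion = fusion,
                 decoderLSTM = decStack, head = H2 + 1)
  structure(sum(breakdown), breakdown = breakdown)
}

#' Embed a batch of secondary-structure condition codes
#'
#' Learnable token embedding with position information injected by a
#' learnable rotary embedding; pad positions (code 0) embed to the zero
#' vector.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param ssCodes integer matrix [batch, seqLen] with entries in 0..8.
#' @return Numeric array [batch, seqLen, condEmbedDim].
#' @export
embedCondition <- function(model, ssCodes) {
  out <- .embedConditionFwd(model@params, model@config, ssCodes)
  out$y
}

.embedConditionFwd <- function(params, config, ssCodes) {
  if (is.vector(ssCodes)) ssCodes <- matrix(ssCodes, nrow = 1)
  B <- nrow(ssCodes); T <- ncol(ssCodes)
  if (T != config@seqLen) {
    stop(sprintf("condition codes must be padded to seqLen = %d", config@seqLen),
         call. = FALSE)
  }
  if (any(ssCodes < 0 | ssCodes > config@condVocab)) {
    stop(sprintf("condition code outside 0..%d", config@condVocab), call. = FALSE)
  }
  emb <- embeddingFwd(ssCodes + 1L, params$condEmbed$E)
  # shift maps pad to the pinned zero row 1
  pos <- rep(seq_len(T), each = B)
  rp <- ropeFwd(emb$y, params$rope$logFreq, pos)
  padMask <- as.vector(ssCodes) == 0L
  y <- rp$y
  y[padMask, ] <- 0
  list(y = matToTensor(y, B, T),
       cache = list(emb = emb$cache, rope = rp$cache, padMask = padMask,
                    B = B, T = T))
}

.embedConditionBwd <- function(dy3, params, cache) {
  dm <- tensorToMat(dy3)
  dm[cache$padMask, ] <- 0
  rb <- ropeBwd(dm, params$rope$logFreq, cache$rope)
  dE <- embeddingBwd(rb$dx, params$condEmbed$E, cache$emb)
  dE[1, ] <- 0  # pad row stays pinned
  list(condEmbed = list(E = dE), rope = list(logFreq = rb$dLogFreq))
}

#' Initial recurrent states from the noise level
#'
#' The scalar noise level, repeated and padded into a
#' [layers x directions, batch, hidden] tensor, serves as the encoder's
#' initial cell state; a learnable tensor broadcast across the batch serves
#' as its initial hidden state.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param noiseLevel scalar noise level in [0, 1).
#' @param batch batch size.
#' @return List with elements \code{hidden} and \code{cell}, both
#'   [2 x layers, batch, hidden].
#' @export
buildInitialStates <- function(model, noiseLevel, batch) {
  cfg <- model@config
  L2 <- 2L * cfg@lstmLayers
  H <- cfg@lstmHidden
  cell <- array(noiseLevel, c(L2, batch, H))
  hidden <- array(0, c(L2, batch, H))
  for (b in seq_len(batch)) hidden[, b, ] <- model@params$h0[, 1, ]
  list(hidden = hidden, cell = cell)
}

## ---- transformer blocks ------------------------------------------------------

.condBlockFwd <- function(x3, p, heads, dropout, training) {
  B <- dim(x3)[1]; T <- dim(x3)[2]
  xm <- tensorToMat(x3)
  ln1 <- layerNormFwd(xm, p$ln1$g, p$ln1$b)
  q <- linearFwd(ln1$y, p$Wq, p$bq)
  k <- linearFwd(ln1$y, p$Wk, p$bk)
  v <- linearFwd(ln1$y, p$Wv, p$bv)
  at <- attentionFwd(matToTensor(q$y, B, T), matToTensor(k$y, B, T),
                     matToTensor(v$y, B, T), heads)
  ao <- linearFwd(tensorToMat(at$y), p$Wo, p$bo)
  d1 <- dropoutFwd(ao$y, dropout, training)
  x1 <- xm + d1$y
  ln2 <- layerNormFwd(x1, p$ln2$g, p$ln2$b)
  f1 <- linearFwd(ln2$y, p$W1, p$b1)
  r <- reluFwd(f1$y)
  f2 <- linearFwd(r$y, p$W2, p$b2)
  d2 <- dropoutFwd(f2$y, dropout, training)
  x2 <- x1 + d2$y
  list(y = matToTensor(x2, B, T),
       cache = list(ln1 = ln1$cache, q = q$cache, k = k$cache, v = v$cache,
                    at = at$cache, ao = ao$cache, d1 = d1$cache,
                    ln2 = ln2$cache, f1 = f1$cache, r = r$cache,
                    f2 = f2$cache, d2 = d2$cache, B = B, T = T))
}

.condBlockBwd <- function(dy3, p, cache) {
  B <- cache$B; T <- cache$T
  dx2 <- tensorToMat(dy3)
  dd2 <- dropoutBwd(dx2, cache$d2)
  g2 <- linearBwd(dd2, p$W2, cache$f2)
  dr <- reluBwd(g2$dx, cache$r)
  g1 <- linearBwd(dr, p$W1, cache$f1)
  lb2 <- layerNormBwd(g1$dx, p$ln2$g, cache$ln2)
  dx1 <- dx2 + lb2$dx
  dd1 <- dropoutBwd(dx1, cache$d1)
  go <- linearBwd(dd1, p$Wo, cache$ao)
  ab <- attentionBwd(matToTensor(go$dx, B, T), cache$at)
  gq <- linearBwd(tensorToMat(ab$dq), p$Wq, cache$q)
  gk <- linearBwd(tensorToMat(ab$dk), p$Wk, cache$k)
  gv <- linearBwd(tensorToMat(ab$dv), p$Wv, cache$v)
  lb1 <- layerNormBwd(gq$dx + gk$dx + gv$dx, p$ln1$g, cache$ln1)
  dxm <- dx1 + lb1$dx
  grads <- list(ln1 = list(g = lb1$dg, b = lb1$db),
                Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                Wv = gv$dW, bv = gv$db, Wo = go$dW, bo = go$db,
                ln2 = list(g = lb2$dg, b = lb2$db),
                W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
  list(dx = matToTensor(dxm, B, T), grads = grads)
}

.fusionFwd <- function(latm, condm, B, T, p, heads, dropout, training) {
  lnq <- layerNormFwd(latm, p$lnq$g, p$lnq$b)
  q <- linearFwd(lnq$y, p$Wq, p$bq)
  k <- linearFwd(condm, p$Wk, p$bk)
  v <- linearFwd(condm, p$Wv, p$bv)
  at <- attentionFwd(matToTensor(q$y, B, T), matToTensor(k$y, B, T),
                     matToTensor(v$y, B, T), heads)
  ao <- linearFwd(tensorToMat(at$y), p$Wo, p$bo)
  d1 <- dropoutFwd(ao$y, dropout, training)
  lat1 <- latm + d1$y
  lnf <- layerNormFwd(lat1, p$lnf$g, p$lnf$b)
  f1 <- linearFwd(lnf$y, p$W1, p$b1)
  r <- reluFwd(f1$y)
  f2 <- linearFwd(r$y, p$W2, p$b2)
  d2 <- dropoutFwd(f2$y, dropout, training)
  lat2 <- lat1 + d2$y
  list(y = lat2,
       cache = list(lnq = lnq$cache, q = q$cache, k = k$cache, v = v$cache,
                    at = at$cache, ao = ao$cache, d1 = d1$cache,
                    lnf = lnf$cache, f1 = f1$cache, r = r$cache,
                    f2 = f2$cache, d2 = d2$cache, B = B, T = T))
}

.fusionBwd <- function(dym, p, cache) {
  B <- cache$B; T <- cache$T
  dlat2 <- dym
  dd2 <- dropoutBwd(dlat2, cache$d2)
  g2 <- linearBwd(dd2, p$W2, cache$f2)
  dr <- reluBwd(g2$dx, cache$r)
  g1 <- linearBwd(dr, p$W1, cache$f1)
  lbf <- layerNormBwd(g1$dx, p$lnf$g, cache$lnf)
  dlat1 <- dlat2 + lbf$dx
  dd1 <- dropoutBwd(dlat1, cache$d1)
  go <- linearBwd(dd1, p$Wo, cache$ao)
  ab <- attentionBwd(matToTensor(go$dx, B, T), cache$at)
  gq <- linearBwd(tensorToMat(ab$dq), p$Wq, cache$q)
  gk <- linearBwd(tensorToMat(ab$dk), p$Wk, cache$k)
  gv <- linearBwd(tensorToMat(ab$dv), p$Wv, cache$v)
  lbq <- layerNormBwd(gq$dx, p$lnq$g, cache$lnq)
  dlatm <- dlat1 + lbq$dx
  dcondm <- gk$dx + gv$dx
  grads <- list(lnq = list(g = lbq$dg, b = lbq$db),
                Wq = gq$dW, bq = gq$db, Wk = gk$dW, bk = gk$db,
                Wv = gv$dW, bv = gv$db, Wo = go$dW, bo = go$db,
                lnf = list(g = lbf$dg, b = lbf$db),
                W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
  list(dlat = dlatm, dcond = matToTensor(dcondm, B, T), grads = grads)
}

## ---- full denoiser forward / backward ---------------------------------------

.denoiserFwd <- function(params, config, xNoised, condEmb3, noiseLevel,
                         training = FALSE) {
  if (is.vector(xNoised)) xNoised <- matrix(xNoised, nrow = 1)
  B <- nrow(xNoised); T <- ncol(xNoised)
  if (T != config@seqLen) stop("noised input width must equal seqLen (denoiser encoder)", call. = FALSE)
  if (!all(dim(condEmb3) == c(B, T, config@condEmbedDim))) {
    stop("condition embedding shape mismatch (condition branch)", call. = FALSE)
  }
  H <- config@lstmHidden; L <- config@lstmLayers
  xm <- matrix(as.vector(xNoised), ncol = 1)  # [B*T, 1], rows (b, t)
  c0 <- array(noiseLevel, c(2 * L, B, H))
  h0 <- array(0, c(2 * L, B, H))
  for (b in seq_len(B)) h0[, b, ] <- params$h0[, 1, ]
  enc <- lstmStackFwd(xm, B, T, params$encoderLSTM, h0, c0)
  cond <- condEmb3
  condCaches <- vector("list", length(params$condEncoder))
  for (i in seq_along(params$condEncoder)) {
    blk <- .condBlockFwd(cond, params$condEncoder[[i]], config@attnHeads,
                         config@dropout, training)
    cond <- blk$y
    condCaches[[i]] <- blk$cache
  }
  fus <- .fusionFwd(enc$y, tensorToMat(cond), B, T, params$fusion,
                    config@attnHeads, config@dropout, training)
  dec <- lstmStackFwd(fus$y, B, T, params$decoderLSTM, enc$hFinal, enc$cFinal)
  hd <- linearFwd(dec$y, params$head$W, params$head$b)
  y <- matrix(hd$y, B, T)
  list(y = y,
       cache = list(enc = enc, condCaches = condCaches, fus = fus, dec = dec,
                    hd = hd$cache, B = B, T = T))
}

.denoiserBwd <- function(dY, params, config, cache) {
  B <- cache$B; T <- cache$T
  gh <- linearBwd(matrix(as.vector(dY), B * T, 1), params$head$W, cache$hd)
  L2 <- 2 * config@lstmLayers
  zeroState <- array(0, c(L2, B, config@lstmHidden))
  decB <- lstmStackBwd(gh$dx, zeroState, zeroState, params$decoderLSTM,
                       cache$dec$caches)
  fusB <- .fusionBwd(decB$dx, params$fusion, cache$fus$cache)
  dcond <- fusB$dcond
  condGrads <- vector("list", length(params$condEncoder))
  for (i in rev(seq_along(params$condEncoder))) {
    blkB <- .condBlockBwd(dcond, params$condEncoder[[i]],
                          cache$condCaches[[i]])
    dcond <- blkB$dx
    condGrads[[i]] <- blkB$grads
  }
  # decoder initial states were the encoder's final states: route those
  # gradients back into the encoder BPTT
  encB <- lstmStackBwd(fusB$dlat, decB$dh0, decB$dc0, params$encoderLSTM,
                       cache$enc$caches)
  dh0 <- array(0, dim(params$h0))
  for (r in seq_len(dim(dh0)[1])) {  # learnable h0 is batch-broadcast
    dh0[r, 1, ] <- colSums(matrix(encB$dh0[r, , ], B))
  }
  grads <- list(condEmbed = NULL, rope = NULL, condEncoder = condGrads,
                encoderLSTM = encB$grads, h0 = dh0, fusion = fusB$grads,
                decoderLSTM = decB$grads,
                head = list(W = gh$dW, b = gh$db))
  list(grads = grads, dCondEmb = dcond)
}

#' Run the denoiser
#'
#' Predicts the clean encoded sequence from a noised one at a given noise
#' level, conditioned on embedded secondary structure. Evaluation mode
#' (deterministic; no dropout).
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param noised numeric matrix [batch, seqLen] (or a vector for batch 1).
#' @param condEmb numeric array [batch, seqLen, condEmbedDim], e.g. from
#'   \code{\link{embedCondition}}.
#' @param noiseLevel scalar noise level \eqn{\sqrt{1-\bar\alpha_t}}.
#' @return Numeric matrix [batch, seqLen].
#' @export
denoise <- function(model, noised, condEmb, noiseLevel) {
  .denoiserFwd(model@params, model@config, noised, condEmb, noiseLevel,
               training = FALSE)$y
}

#' Condition dropout along the sequence-length dimension
#'
#' Independently zeroes each condition position (the whole embedding vector
#' at once) with probability p. Used during training so the model jointly
#' learns conditional and unconditional denoising; p = 1 gives the fully
#' unconditional input used by classifier-free guidance at sampling time.
#'
#' @param condEmb numeric array [batch, seqLen, condEmbedDim].
#' @param p dropout probability in [0, 1].
#' @return Array of the same shape (attribute \code{"mask"} holds the kept
#'   positions, [batch, seqLen]).
#' @export
applyConditionDropout <- function(condEmb, p) {
  stopifnot(p >= 0, p <= 1)
  B <- dim(condEmb)[1]; T <- dim(condEmb)[2]
  keep <- matrix(runif(B * T) >= p, B, T)
  out <- condEmb * as.vector(keep)  # broadcasts over the embedding axis
  structure(out, mask = keep)
}
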