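## Two-phase training: staged dataset expansion with Adam and an exponential
## learning-rate decay, then fine-tuning with selective freezing, plus
## generation-based early stopping and checkpointing.

#' Training configuration
#'
#' @param lrStart initial Adam learning rate (1e-4).
#' @param lrEnd final learning rate (1e-7); the decay is exponential in the
#'   step index and hits \code{lrEnd} exactly at the last scheduled step.
#' @param batchSize sequences per batch.
#' @param epochs epochs per phase.
#' @param datasetFractions increasing staged fractions of the corpus
#'   (default 0.25, 0.65, 0.95); the last fraction is the fine-tuning stage.
#' @param pretrainLossGate loss level below which pretraining may hand over
#'   to fine-tuning (NA disables the gate, the default at desk scale).
#' @param seed run seed; every source of randomness derives from it.
#' @param earlyStopPatience checkpoints without improvement tolerated before
#'   stopping.
#' @return A \code{\linkS4class{TrainConfig}}.
#' @export
trainConfig <- function(lrStart = 1e-4, lrEnd = 1e-7, batchSize = 16L,
                        epochs = 2L, datasetFractions = c(0.25, 0.65, 0.95),
                        pretrainLossGate = NA_real_, seed = 1L,
                        earlyStopPatience = 3L) {
  new("TrainConfig", lrStart = lrStart, lrEnd = lrEnd,
      batchSize = as.integer(batchSize), epochs = as.integer(epochs),
      datasetFractions = datasetFractions, pretrainLossGate = pretrainLossGate,
      seed = as.integer(seed), earlyStopPatience = as.integer(earlyStopPatience))
}

#' Learning rate at a scheduled step
#'
#' Exponential decay from \code{lrStart} to \code{lrEnd}:
#' \eqn{lr(s) = lr_{start} (lr_{end}/lr_{start})^{(s-1)/(S-1)}}.
#'
#' @param step step index in 1..totalSteps.
#' @param totalSteps number of scheduled steps.
#' @param lrStart,lrEnd endpoints.
#' @return The learning rate.
#' @export
lrAt <- function(step, totalSteps, lrStart = 1e-4, lrEnd = 1e-7) {
  if (totalSteps <= 1) return(lrEnd)
  lrStart * (lrEnd / lrStart)^((step - 1) / (totalSteps - 1))
}

#' Nested staged training subsets
#'
#' Draws one random permutation of the corpus under \code{seed} and takes
#' growing prefixes of it, so each later subset contains all earlier ones
#' (sizes are \code{round(fraction * n)}).
#'
#' @param corpus a \code{\linkS4class{PolypeptideSet}}.
#' @param fractions increasing fractions in (0, 1].
#' @param seed integer seed.
#' @return List of \code{PolypeptideSet} subsets.
#' @export
stagedSubsets <- function(corpus, fractions, seed = 1L) {
  n <- length(corpus)
  if (n == 0) stop("corpus is empty", call. = FALSE)
  if (any(diff(fractions) <= 0)) stop("fractions must be increasing", call. = FALSE)
  perm <- withSeed(seed, sample.int(n))
  lapply(fractions, function(f) {
    k <- max(1L, round(f * n))
    new("PolypeptideSet", records = corpus@records[sort(perm[seq_len(k)]), ,
                                                   drop = FALSE])
  })
}

## Encode a record set into model-ready matrices: clean normalized values
## x0 [n, seqLen] and padded condition codes [n, seqLen].
encodeRecords <- function(records, seqLen) {
  n <- length(records)
  x0 <- matrix(0, n, seqLen)
  cond <- matrix(0L, n, seqLen)
  aa <- aaSeqs(records); ss <- ssSeqs(records)
  for (i in seq_len(n)) {
    es <- normalizeAndPad(encodeAA(aa[i]), 20L, seqLen)
    x0[i, ] <- seqValues(es)
    codes <- encodeSS(ss[i])
    cond[i, seq_along(codes)] <- codes
  }
  list(x0 = x0, cond = cond)
}

## ---- Adam -------------------------------------------------------------------

adamInit <- function(params) {
  list(m = zerosLike(params), v = zerosLike(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, trainable,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (grp in names(params)) {
    if (!(grp %in% trainable)) next
    state$m[[grp]] <- paramZip(state$m[[grp]], grads[[grp]],
                               function(m, g) beta1 * m + (1 - beta1) * g)
    state$v[[grp]] <- paramZip(state$v[[grp]], grads[[grp]],
                               function(v, g) beta2 * v + (1 - beta2) * g^2)
    upd <- paramZip(state$m[[grp]], state$v[[grp]],
                    function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
    params[[grp]] <- paramZip(params[[grp]], upd, function(p, u) p - u)
  }
  list(params = params, state = state)
}

## ---- one training step ------------------------------------------------------
## Shared batch timestep, closed-form corruption, condition dropout, x0
## prediction, MSE; returns loss and the full gradient structure.

trainStepGrads <- function(params, config, schedule, x0, cond) {
  t <- sampleBatchTimestep(schedule)
  eps <- matrix(rnorm(length(x0)), nrow(x0))
  xNoised <- forwardClosedForm(x0, t, eps, schedule)
  nl <- noiseLevelAt(schedule, t)
  embF <- .embedConditionFwd(params, config, cond)
  dropped <- applyConditionDropout(embF$y, config@condDropoutProb)
  keep <- attr(dropped, "mask")
  fwd <- .denoiserFwd(params, config, xNoised, dropped, nl, training = TRUE)
  loss <- trainingLoss(fwd$y, x0)
  dY <- 2 * (fwd$y - x0) / length(x0)
  bwd <- .denoiserBwd(dY, params, config, fwd$cache)
  dEmb <- bwd$dCondEmb * as.vector(keep)  # dropout mask gates the embedding grad
  embGrads <- .embedConditionBwd(dEmb, params, embF$cache)
  bwd$grads$condEmbed <- embGrads$condEmbed
  bwd$grads$rope <- embGrads$rope
  list(loss = loss, grads = bwd$grads, t = t)
}

#' Train for one phase
#'
#' Runs \code{epochs} passes over the subset in shuffled mini-batches. Each
#' batch samples one shared diffusion timestep, corrupts the clean encoded
#' sequences in closed form, applies condition dropout, predicts the clean
#' sequence with the denoiser, and takes an Adam step on the mean-squared
#' error; the learning rate decays exponentially from \code{lrStart} to
#' \code{lrEnd} over the phase's scheduled steps. Only the model's currently
#' trainable groups are updated. Aborts on non-finite loss.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param subset a \code{\linkS4class{PolypeptideSet}}.
#' @param config a \code{\linkS4class{TrainConfig}}.
#' @param schedule optional \code{\linkS4class{NoiseSchedule}} override
#'   (defaults to the model's own schedule).
#' @param steps optional cap on total optimization steps.
#' @return List: \code{model} (trained), \code{lossCurve} (per-step numeric),
#'   \code{epochLoss} (mean loss per epoch).
#' @export
trainPhase <- function(model, subset, config, schedule = NULL, steps = NULL) {
  if (length(subset) == 0) stop("training subset is empty", call. = FALSE)
  if (is.null(schedule)) schedule <- model@schedule
  cfg <- model@config
  enc <- encodeRecords(subset, cfg@seqLen)
  n <- nrow(enc$x0)
  batchesPerEpoch <- max(1L, ceiling(n / config@batchSize))
  totalSteps <- config@epochs * batchesPerEpoch
  if (!is.null(steps)) totalSteps <- min(totalSteps, as.integer(steps))
  params <- model@params
  state <- adamInit(params)
  lossCurve <- numeric(0)
  withSeed(config@seed, {
    step <- 0L
    done <- FALSE
    for (ep in seq_len(config@epochs)) {
      if (done) break
      ord <- sample.int(n)
      for (bi in seq_len(batchesPerEpoch)) {
        idx <- ord[((bi - 1L) * config@batchSize + 1L):min(bi * config@batchSize, n)]
        sg <- trainStepGrads(params, cfg, schedule,
                             enc$x0[idx, , drop = FALSE],
                             enc$cond[idx, , drop = FALSE])
        if (!is.finite(sg$loss)) {
          stop(sprintf("training diverged: non-finite loss at step %d", step + 1L),
               call. = FALSE)
        }
        step <- step + 1L
        lr <- lrAt(step, totalSteps, config@lrStart, config@lrEnd)
        up <- adamStep(params, sg$grads, state, lr, model@trainable)
        params <- up$params
        state <- up$state
        lossCurve <- c(lossCurve, sg$loss)
        if (step >= totalSteps) { done <- TRUE; break }
      }
    }
  })
  model@params <- params
  epochLoss <- vapply(split(lossCurve, ceiling(seq_along(lossCurve) / batchesPerEpoch)),
                      mean, numeric(1))
  list(model = model, lossCurve = lossCurve, epochLoss = unname(epochLoss))
}

#' Selective freezing for fine-tuning
#'
#' \code{freezeForFinetune} restricts backpropagation to the LSTM stacks of
#' the encoder and decoder, the cross-attention fusion block and the final
#' dense head; the condition embedding, rotary frequencies, condition
#' transformer encoder and learnable initial hidden state are frozen.
#' \code{unfreeze} restores full trainability.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @return The model with its trainability mask updated.
#' @export
freezeForFinetune <- function(model) {
  model@trainable <- c("encoderLSTM", "decoderLSTM", "fusion", "head")
  model
}

#' @rdname freezeForFinetune
#' @export
unfreeze <- function(model) {
  model@trainable <- names(model@params)
  model
}

#' Generation-based early stopping rule
#'
#' Stop once the generation score has failed to improve for
#' \code{patience} consecutive checkpoints; the best checkpoint index is
#' retained.
#'
#' @param scores numeric history of per-checkpoint generation scores (higher
#'   is better).
#' @param patience consecutive non-improving checkpoints tolerated.
#' @return List: \code{stop} (logical) and \code{best} (index of the best
#'   checkpoint so far).
#' @examples
#' earlyStoppingMonitor(c(0.5, 0.6, 0.55, 0.54), patience = 2)
#' @export
earlyStoppingMonitor <- function(scores, patience) {
  if (length(scores) == 0) return(list(stop = FALSE, best = NA_integer_))
  best <- which.max(scores)
  list(stop = (length(scores) - best) >= patience, best = best)
}

#' Full staged training pipeline
#'
#' Phase one trains all parameters on the growing pretraining subsets; once
#' the final pretraining stage completes (or the loss gate is reached), the
#' model is frozen for fine-tuning and trained on the largest subset. If a
#' \code{scoreFun} is supplied, it is called after every fine-tuning epoch
#' and drives early stopping; the best-scoring parameters are kept.
#'
#' @param model a freshly initialized \code{\linkS4class{PepDenoiser}}.
#' @param corpus a \code{\linkS4class{PolypeptideSet}}.
#' @param config a \code{\linkS4class{TrainConfig}}.
#' @param scoreFun optional function(model) -> numeric generation score.
#' @return List: \code{model}, \code{history} (per-phase loss curves),
#'   \code{scores} (fine-tune score history, if scored).
#' @export
fitDenoiser <- function(model, corpus, config, scoreFun = NULL) {
  subsets <- stagedSubsets(corpus, config@datasetFractions, config@seed)
  history <- list()
  nPre <- length(subsets) - 1L
  for (i in seq_len(nPre)) {
    ph <- trainPhase(model, subsets[[i]], config)
    model <- ph$model
    history[[paste0("pretrain", i)]] <- ph$lossCurve
    gate <- config@pretrainLossGate
    if (!is.na(gate) && mean(utils::tail(ph$lossCurve, 10)) <= gate) break
  }
  model <- freezeForFinetune(model)
  scores <- numeric(0)
  bestParams <- model@params
  fineSubset <- subsets[[length(subsets)]]
  for (ep in seq_len(config@epochs)) {
    epCfg <- config
    epCfg@epochs <- 1L
    epCfg@seed <- deriveSeed(config@seed, paste0("finetune", ep))
    ph <- trainPhase(model, fineSubset, epCfg)
    model <- ph$model
    history[[paste0("finetune", ep)]] <- ph$lossCurve
    if (!is.null(scoreFun)) {
      scores <- c(scores, scoreFun(model))
      mon <- earlyStoppingMonitor(scores, config@earlyStopPatience)
      if (mon$best == length(scores)) bestParams <- model@params
      if (mon$stop) break
    }
  }
  if (!is.null(scoreFun) && length(scores) > 0) model@params <- bestParams
  model <- unfreeze(model)
  list(model = model, history = history, scores = scores)
}

## ---- checkpoints ------------------------------------------------------------

#' Save and load model checkpoints
#'
#' A checkpoint bundles the weights with the full architecture
#' configuration, both codebooks and the noise schedule, so loading verifies
#' compatibility and save/load/generate is bit-reproducible.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param path file path (RDS).
#' @return \code{loadCheckpoint} returns the restored
#'   \code{\linkS4class{PepDenoiser}}.
#' @export
saveCheckpoint <- function(model, path) {
  obj <- list(
    format = "pepdiff-checkpoint-1",
    config = sapply(slotNames(model@config), function(s) slot(model@config, s),
                    simplify = FALSE),
    alphabets = list(ss = ssAlphabet(), aa = aaAlphabet()),
    schedule = list(timesteps = model@schedule@timesteps,
                    alphaBar = model@schedule@alphaBar),
    trainable = model@trainable,
    params = model@params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "pepdiff-checkpoint-1")) {
    stop("not a recognized checkpoint file", call. = FALSE)
  }
  if (!identical(obj$alphabets$ss, ssAlphabet()) ||
      !identical(obj$alphabets$aa, aaAlphabet())) {
    stop("checkpoint alphabets are incompatible with this package version",
         call. = FALSE)
  }
  cfg <- do.call(denoiserConfig, obj$config[setdiff(names(obj$config),
                                                    "bidirectional")])
  sched <- new("NoiseSchedule", timesteps = obj$schedule$timesteps,
               alphaBar = obj$schedule$alphaBar)
  new("PepDenoiser", config = cfg, params = obj$params, schedule = sched,
      trainable = obj$trainable)
}
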