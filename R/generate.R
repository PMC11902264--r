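## Reverse-process generation: iterative denoise / guidance / re-noise /
## correction refinement from pure Gaussian noise, then quantization back to
## residues.

#' Generate a polypeptide sequence under a secondary-structure condition
#'
#' Starts from a standard-normal array of the model's padded width. Each
#' refinement iteration runs the denoiser twice - once with the embedded
#' condition and once with the condition masked to zero - combines the two
#' clean-sequence estimates by classifier-free guidance
#' (\code{\link{cfgCombine}}), re-injects scheduled Gaussian noise at the
#' next noise level (scaled by \code{extraNoiseScale}, the creativity knob),
#' and corrects by clamping to the valid normalized range [-1, 1]. After the
#' final iteration the first \code{nchar(condition)} positions are quantized
#' to residues.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param condition a DSSP-alphabet condition string (length <= seqLen).
#' @param settings a \code{\linkS4class{GenerationSettings}}.
#' @param denoiserFun optional replacement denoiser
#'   \code{function(noised, condEmb, noiseLevel) -> [1, seqLen]} (used by the
#'   oracle-denoiser diagnostics; defaults to the model's network).
#' @return List with elements \code{record} (one-row
#'   \code{\linkS4class{PolypeptideSet}}: generated sequence paired with the
#'   condition), and \code{trace} (per-iteration timestep, noise level and
#'   quantized clean-sequence estimate).
#' @examples
#' m <- newDenoiser(tinyDenoiserConfig(), cosineSchedule(8), seed = 1)
#' g <- generateSequence(m, "--HHHHHH--", generationSettings(steps = 8, seed = 2))
#' aaSeqs(g$record)
#' @export
generateSequence <- function(model, condition, settings = generationSettings(),
                             denoiserFun = NULL) {
  cfg <- model@config
  L <- nchar(condition)
  if (L > cfg@seqLen) {
    stop(sprintf("condition of length %d exceeds the %d-residue cap",
                 L, cfg@seqLen), call. = FALSE)
  }
  codes <- encodeSS(condition)
  condRow <- matrix(0L, 1, cfg@seqLen)
  condRow[1, seq_len(L)] <- codes
  condEmb <- embedCondition(model, condRow)
  zeroEmb <- array(0, dim(condEmb))
  if (is.null(denoiserFun)) {
    denoiserFun <- function(noised, emb, nl) denoise(model, noised, emb, nl)
  }
  sched <- model@schedule
  T <- nTimesteps(sched)
  steps <- settings@steps
  ## map the refinement iterations onto schedule timesteps (identity when
  ## steps == T, the default pairing)
  ts <- as.integer(round(seq(T, 1, length.out = steps)))
  W <- settings@conditionScale
  ab <- alphaBar(sched)
  trace <- data.frame(iteration = seq_len(steps), t = ts,
                      noiseLevel = sqrt(1 - ab[ts + 1L]))
  x0codes <- matrix(0L, steps, L)
  x <- NULL
  withSeed(settings@seed, {
    x <- rnorm(cfg@seqLen)
    for (i in seq_len(steps)) {
      t <- ts[i]
      nl <- sqrt(1 - ab[t + 1L])
      yc <- denoiserFun(matrix(x, 1), condEmb, nl)
      yu <- denoiserFun(matrix(x, 1), zeroEmb, nl)
      x0hat <- as.vector(cfgCombine(yc, yu, W))
      x0codes[i, ] <- quantizeValues(x0hat, 20L, L)
      tNext <- if (i < steps) ts[i + 1L] - 1L else 0L
      tNext <- max(tNext, 0L)
      abNext <- ab[tNext + 1L]
      fresh <- settings@extraNoiseScale * rnorm(cfg@seqLen)
      x <- sqrt(abNext) * x0hat + sqrt(1 - abNext) * fresh
      x <- pmin(pmax(x, -1), 1)  # correction keeping values in range
    }
  })
  aa <- decodeAA(quantizeValues(x, 20L, L))
  rec <- new("PolypeptideSet", records = data.frame(
    sourceId = sprintf("gen_seed%d_W%g", settings@seed, W),
    aa = aa, ss = condition, length = L, stringsAsFactors = FALSE))
  list(record = rec, trace = trace, x0codes = x0codes)
}
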