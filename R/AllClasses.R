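#' @import methods
NULL

#' Fixed-length normalized encoding of a residue sequence
#'
#' Holds the numeric representation a diffusion model operates on: integer
#' residue codes mapped linearly into (-1, 1) and right-padded with zeros to a
#' uniform length (250 by default). Zero is reserved for padding and is never
#' a valid normalized code value, so true length is recoverable.
#'
#' @slot values numeric vector of fixed length (\code{maxLen}); entries at or
#'   beyond \code{length} are exactly 0.
#' @slot length integer; true residue count.
#' @slot alphabetSize integer; size K of the code alphabet (20 for residues).
#' @exportClass EncodedSequence
setClass("EncodedSequence",
  representation(values = "numeric", length = "integer",
                 alphabetSize = "integer"))

setValidity("EncodedSequence", function(object) {
  n <- object@length
  v <- object@values
  if (length(n) != 1L || n < 1L) return("length must be a single positive integer")
  if (n > length(v)) return("length exceeds the padded array size")
  if (any(v[seq_len(n)] == 0)) return("in-sequence positions must not be 0")
  if (n < length(v) && any(v[(n + 1L):length(v)] != 0)) {
    return("padding positions must hold exactly 0")
  }
  valid <- normalizedCodeValues(object@alphabetSize)
  if (!all(v[seq_len(n)] %in% valid)) {
    return("in-sequence values must be normalized code values")
  }
  TRUE
})

#' Diffusion noise schedule
#'
#' Cumulative signal-retention fractions \eqn{\bar\alpha_t} for a variance-
#' preserving diffusion over \code{timesteps} steps, with
#' \eqn{\bar\alpha_0 = 1} (clean data) decreasing strictly to near 0 at the
#' terminal step.
#'
#' @slot timesteps integer; number of diffusion timesteps T.
#' @slot alphaBar numeric vector of length T + 1; \code{alphaBar[t + 1]} is
#'   \eqn{\bar\alpha_t}.
#' @exportClass NoiseSchedule
setClass("NoiseSchedule",
  representation(timesteps = "integer", alphaBar = "numeric"))

setValidity("NoiseSchedule", function(object) {
  ab <- object@alphaBar
  T <- object@timesteps
  if (length(ab) != T + 1L) return("alphaBar must have length timesteps + 1")
  if (ab[1] != 1) return("alphaBar[0] must equal 1")
  if (any(diff(ab) >= 0)) return("alphaBar must be strictly decreasing")
  if (any(ab <= 0) || any(ab > 1)) return("alphaBar must lie in (0, 1]")
  if (ab[T + 1L] >= 0.01) return("terminal alphaBar must be below 0.01 (near-pure noise)")
  TRUE
})

#' Reverse-process generation settings
#'
#' @slot steps integer; refinement iterations of the reverse loop (default 64).
#' @slot conditionScale numeric; classifier-free-guidance weight W (default 1).
#' @slot seed integer; RNG seed for the whole generation.
#' @slot extraNoiseScale numeric in [0, 1]; scale of the fresh Gaussian noise
#'   re-injected after each denoising step (0 = deterministic refinement).
#' @exportClass GenerationSettings
setClass("GenerationSettings",
  representation(steps = "integer", conditionScale = "numeric",
                 seed = "integer", extraNoiseScale = "numeric"))

setValidity("GenerationSettings", function(object) {
  if (object@steps < 1L) return("steps must be >= 1")
  if (object@conditionScale < 0) return("conditionScale must be >= 0")
  if (object@extraNoiseScale < 0 || object@extraNoiseScale > 1) {
    return("extraNoiseScale must lie in [0, 1]")
  }
  TRUE
})

#' Denoiser architecture hyperparameters
#'
#' @slot seqLen integer; padded sequence length (250).
#' @slot condVocab integer; secondary-structure vocabulary size (8, plus a
#'   reserved 0 pad code).
#' @slot condEmbedDim integer; condition embedding width (256).
#' @slot lstmHidden integer; per-direction LSTM hidden width (512).
#' @slot lstmLayers integer; recurrent layers per stack (6).
#' @slot bidirectional logical; both directions (TRUE); state block leading
#'   dimension is layers x directions (12 under defaults).
#' @slot attnHeads integer; attention heads.
#' @slot transformerBlocks integer; self-attention blocks in the condition
#'   encoder (the fusion stage always uses one cross-attention block).
#' @slot ffDim integer; feed-forward width inside transformer blocks.
#' @slot dropout numeric; transformer dropout probability (training only).
#' @slot condDropoutProb numeric; probability of zeroing each condition
#'   position during training (classifier-free guidance).
#' @exportClass DenoiserConfig
setClass("DenoiserConfig",
  representation(seqLen = "integer", condVocab = "integer",
                 condEmbedDim = "integer", lstmHidden = "integer",
                 lstmLayers = "integer", bidirectional = "logical",
                 attnHeads = "integer", transformerBlocks = "integer",
                 ffDim = "integer", dropout = "numeric",
                 condDropoutProb = "numeric"))

setValidity("DenoiserConfig", function(object) {
  if (object@condEmbedDim %% object@attnHeads != 0) {
    return("condEmbedDim must be divisible by attnHeads")
  }
  if (object@condEmbedDim %% 2 != 0) {
    return("condEmbedDim must be even (rotary embedding rotates pairs)")
  }
  if (object@seqLen < 1L || object@lstmHidden < 1L || object@lstmLayers < 1L) {
    return("seqLen, lstmHidden and lstmLayers must be positive")
  }
  if (object@condDropoutProb < 0 || object@condDropoutProb > 1) {
    return("condDropoutProb must lie in [0, 1]")
  }
  TRUE
})

#' Training procedure configuration
#'
#' @slot lrStart numeric; initial Adam learning rate (1e-4).
#' @slot lrEnd numeric; final learning rate (1e-7).
#' @slot batchSize integer.
#' @slot epochs integer; epochs per phase.
#' @slot datasetFractions numeric; increasing staged dataset fractions.
#' @slot pretrainLossGate numeric; loss level gating the move to fine-tuning
#'   (NA disables the gate).
#' @slot seed integer.
#' @slot earlyStopPatience integer; checkpoints without improvement tolerated.
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(lrStart = "numeric", lrEnd = "numeric", batchSize = "integer",
                 epochs = "integer", datasetFractions = "numeric",
                 pretrainLossGate = "numeric", seed = "integer",
                 earlyStopPatience = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@lrEnd >= object@lrStart) return("lrEnd must be below lrStart")
  f <- object@datasetFractions
  if (any(f <= 0) || any(f > 1)) return("datasetFractions must lie in (0, 1]")
  if (length(f) > 1 && any(diff(f) <= 0)) return("datasetFractions must be increasing")
  TRUE
})

#' Synthetic corpus grammar
#'
#' Defines a stochastic map from secondary-structure class to residue
#' identity, plus a segmenter producing secondary-structure strings as
#' alternating H/E/- segments with geometric lengths. Stands in for a
#' PDB-derived corpus so the full pipeline is trainable offline.
#'
#' @slot emission named list; one categorical distribution over the 20
#'   residues per DSSP class (names are DSSP characters).
#' @slot lengthRange integer vector length 2; min/max sequence length.
#' @slot segMeanStructured numeric; mean geometric segment length for H/E.
#' @slot segMeanCoil numeric; mean geometric segment length for coil.
#' @exportClass GrammarSpec
setClass("GrammarSpec",
  representation(emission = "list", lengthRange = "integer",
                 segMeanStructured = "numeric", segMeanCoil = "numeric"))

setValidity("GrammarSpec", function(object) {
  ssChars <- names(ssAlphabet())
  if (!all(ssChars %in% names(object@emission))) {
    return("emission must cover all 8 DSSP classes")
  }
  aaChars <- names(aaAlphabet())
  for (cls in names(object@emission)) {
    p <- object@emission[[cls]]
    if (!all(names(p) %in% aaChars)) return("emission support must be standard residues")
    if (abs(sum(p) - 1) > 1e-9) return("each emission distribution must sum to 1")
    if (any(p < 0)) return("emission probabilities must be non-negative")
  }
  lr <- object@lengthRange
  if (lr[1] < 1L || lr[2] > 250L || lr[1] > lr[2]) {
    return("lengthRange must lie within [1, 250] with min <= max")
  }
  TRUE
})

#' A set of paired polypeptide records
#'
#' Each record pairs an amino-acid sequence with its per-residue DSSP
#' secondary-structure string of equal length, plus provenance.
#'
#' @slot records data.frame with columns sourceId, aa, ss, length.
#' @exportClass PolypeptideSet
setClass("PolypeptideSet", representation(records = "data.frame"))

setValidity("PolypeptideSet", function(object) {
  df <- object@records
  need <- c("sourceId", "aa", "ss", "length")
  if (!all(need %in% names(df))) {
    return(paste("records must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(df) > 0) {
    if (!all(nchar(df$aa) == df$length)) return("aa length mismatch")
    if (!all(nchar(df$ss) == df$length)) return("ss length mismatch")
  }
  TRUE
})

#' Upper-triangular pairwise sequence-similarity store
#'
#' @slot n integer; number of sequences.
#' @slot values numeric matrix n x n; percent identities on the upper triangle
#'   (i < j), 100 on the diagonal, NA below (excluded from averages).
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix", representation(n = "integer", values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  if (!all(dim(v) == object@n)) return("values must be n x n")
  up <- v[upper.tri(v)]
  if (any(up < 0 | up > 100, na.rm = TRUE)) return("similarities must lie in [0, 100]")
  if (any(!is.na(v[lower.tri(v)]))) return("lower triangle must be NA")
  TRUE
})

#' The conditional denoising model
#'
#' Bundles architecture configuration, trained weights, the noise schedule
#' and the trainability mask used for selective fine-tuning.
#'
#' @slot config a \code{DenoiserConfig}.
#' @slot params nested named list of numeric arrays (the weights).
#' @slot schedule a \code{NoiseSchedule}.
#' @slot trainable character; names of top-level parameter groups currently
#'   receiving gradients.
#' @exportClass PepDenoiser
setClass("PepDenoiser",
  representation(config = "DenoiserConfig", params = "list",
                 schedule = "NoiseSchedule", trainable = "character"))
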