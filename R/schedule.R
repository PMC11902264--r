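## Diffusion mechanics: noise schedule, forward corruption (closed form and
## stepwise), shared batch timestep sampling, the MSE training objective and
## classifier-free-guidance mixing.

#' Cosine noise schedule
#'
#' Builds the cumulative signal-retention schedule
#' \eqn{\bar\alpha_t = \cos^2((t/T + s)/(1 + s) \cdot \pi/2) / \cos^2(s\pi/(2(1+s)))}
#' with offset \code{s = 0.008}, clipped so \eqn{\bar\alpha_T} sits below
#' 0.01 (near-pure noise) while every entry stays positive. T defaults to 64,
#' matching the 64 refinement iterations of the reverse loop so training and
#' inference see the same noise levels.
#'
#' @param timesteps number of diffusion timesteps T.
#' @param s small offset preventing a degenerate first step.
#' @return A \code{\linkS4class{NoiseSchedule}}.
#' @examples
#' sched <- cosineSchedule(64)
#' alphaBar(sched)[1]   # 1
#' @export
cosineSchedule <- function(timesteps = 64L, s = 0.008) {
  T <- as.integer(timesteps)
  t <- 0:T
  f <- cos(((t / T + s) / (1 + s)) * pi / 2)^2
  ab <- f / f[1]
  ab <- pmin(ab, 1)
  # keep the tail strictly positive and below the near-pure-noise ceiling
  ab[T + 1] <- min(ab[T + 1], 0.0099)
  ab <- pmax(ab, 1e-6)
  ab[1] <- 1
  new("NoiseSchedule", timesteps = T, alphaBar = ab)
}

.abAt <- function(schedule, t) {
  T <- schedule@timesteps
  if (any(t < 0 | t > T)) {
    stop(sprintf("timestep out of range 0..%d", T), call. = FALSE)
  }
  schedule@alphaBar[t + 1L]
}

#' Noise level at a timestep
#'
#' The scalar \eqn{\sqrt{1 - \bar\alpha_t}} passed to the denoiser as its
#' noise-level input.
#'
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param t timestep in 0..T.
#' @return Numeric noise level in [0, 1).
#' @export
noiseLevelAt <- function(schedule, t) sqrt(1 - .abAt(schedule, t))

#' Forward corruption in closed form
#'
#' Collapses t incremental Gaussian corruptions into a single weighted
#' operation: \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon}.
#'
#' @param x0 numeric array; the clean encoded sequence values.
#' @param t timestep in 0..T.
#' @param eps standard-normal draw, same shape as \code{x0}.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @return Corrupted array, same shape as \code{x0}.
#' @examples
#' sched <- cosineSchedule(64)
#' forwardClosedForm(c(0.5, -0.5), 0, c(1, 1), sched)  # returns x0 exactly
#' @export
forwardClosedForm <- function(x0, t, eps, schedule) {
  if (length(eps) != length(x0)) stop("eps shape must match x0", call. = FALSE)
  ab <- .abAt(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' One incremental forward corruption step
#'
#' The Markov single-step corruption from state t-1 to t:
#' \eqn{x_t = \sqrt{\alpha_t}\, x_{t-1} + \sqrt{1-\alpha_t}\,\epsilon} with
#' \eqn{\alpha_t = \bar\alpha_t / \bar\alpha_{t-1}}, so iterating steps 1..t
#' reproduces the closed form in distribution.
#'
#' @param xPrev array; state at timestep t-1.
#' @param t timestep in 1..T.
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @param eps optional standard-normal draw (defaults to a fresh draw).
#' @return Array; state at timestep t.
#' @export
forwardStep <- function(xPrev, t, schedule, eps = rnorm(length(xPrev))) {
  if (t < 1 || t > schedule@timesteps) {
    stop(sprintf("timestep out of range 1..%d", schedule@timesteps), call. = FALSE)
  }
  alphaT <- .abAt(schedule, t) / .abAt(schedule, t - 1L)
  out <- sqrt(alphaT) * xPrev + sqrt(1 - alphaT) * eps
  dim(out) <- dim(xPrev)
  out
}

#' Sample the shared batch timestep
#'
#' One uniform draw from 1..T per training batch, applied to every sequence
#' in the batch (rather than per-sequence sampling).
#'
#' @param schedule a \code{\linkS4class{NoiseSchedule}}.
#' @return A single integer timestep.
#' @export
sampleBatchTimestep <- function(schedule) {
  sample.int(schedule@timesteps, 1L)
}

#' Mean-squared-error training objective
#'
#' \eqn{L = \frac{1}{N}\sum_i (\hat y_i - y_i)^2} over all N = batch size x
#' sequence length elements.
#'
#' @param pred,target numeric arrays of identical shape.
#' @return The scalar loss.
#' @examples
#' trainingLoss(c(1, 2), c(0, 0))  # 2.5
#' @export
trainingLoss <- function(pred, target) {
  if (length(pred) != length(target)) {
    stop("pred and target shapes must match", call. = FALSE)
  }
  mean((pred - target)^2)
}

#' Classifier-free-guidance combination
#'
#' Mixes the conditional and unconditional denoiser outputs:
#' \eqn{x_{CFG} = x_{uncond} + W (x_{cond} - x_{uncond})}. W = 1 adopts the
#' fully conditional result; W = 0 the unconditional one.
#'
#' @param xCond,xUncond arrays of identical shape.
#' @param W condition scale (>= 0).
#' @return The combined array.
#' @examples
#' cfgCombine(c(1, 1), c(0, 0), W = 1)  # conditional branch
#' @export
cfgCombine <- function(xCond, xUncond, W = 1) {
  if (length(xCond) != length(xUncond)) {
    stop("conditional and unconditional shapes must match", call. = FALSE)
  }
  # the endpoint identities hold exactly, untouched by round-off
  if (W == 1) return(xCond)
  if (W == 0) return(xUncond)
  xUncond + W * (xCond - xUncond)
}

#' Reverse-process generation settings
#'
#' @param steps refinement iterations (default 64).
#' @param conditionScale guidance weight W (default 1, fully conditional).
#' @param seed integer RNG seed.
#' @param extraNoiseScale scale in [0, 1] of the fresh Gaussian noise
#'   re-injected each iteration to enhance creativity (default 1).
#' @return A \code{\linkS4class{GenerationSettings}}.
#' @export
generationSettings <- function(steps = 64L, conditionScale = 1,
                               seed = 1L, extraNoiseScale = 1) {
  new("GenerationSettings", steps = as.integer(steps),
      conditionScale = conditionScale, seed = as.integer(seed),
      extraNoiseScale = extraNoiseScale)
}
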