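test_that("configuration validity enforces the architecture constraints", {
  cfg <- denoiserConfig()
  expect_identical(cfg@condEmbedDim, 256L)
  expect_identical(cfg@lstmLayers * 2L, 12L)  # state leading dimension
  expect_error(denoiserConfig(condEmbedDim = 30L, attnHeads = 4L), "divisible")
  expect_silent(validObject(tinyDenoiserConfig()))
})

test_that("parameter counts match the analytic enumeration", {
  for (cfg in list(microConfig(), tinyDenoiserConfig())) {
    m <- newDenoiser(cfg, cosineSchedule(8), seed = 3)
    actual <- countParameters(m)
    analytic <- countParametersConfig(cfg)
    expect_equal(as.numeric(actual), as.numeric(analytic))
    expect_equal(attr(actual, "breakdown")[names(attr(analytic, "breakdown"))],
                 attr(analytic, "breakdown"))
  }
  # embedding contribution under defaults: (8 + 1) x 256, pad row included
  bd <- attr(countParametersConfig(denoiserConfig()), "breakdown")
  expect_equal(unname(bd["condEmbed"]), (8 + 1) * 256)
})

test_that("condition embedding injects position and masks padding", {
  m <- microModel(seed = 13)
  codes <- matrix(c(3L, 3L, 1L, 0L, 0L, 0L), nrow = 1)
  emb <- embedCondition(m, codes)
  expect_identical(dim(emb), c(1L, 6L, 8L))
  # pad positions embed to exact zero vectors
  expect_true(all(emb[1, 4:6, ] == 0))
  # same code at different positions gives different vectors (rotary shift)
  expect_false(isTRUE(all.equal(emb[1, 1, ], emb[1, 2, ])))
  expect_error(embedCondition(m, matrix(9L, 1, 6)), "0..8")
  expect_error(embedCondition(m, matrix(1L, 1, 5)), "seqLen")
})

test_that("initial states carry the noise level and broadcast the hidden", {
  m <- microModel()
  st <- buildInitialStates(m, noiseLevel = 0.37, batch = 3)
  expect_identical(dim(st$cell), c(4L, 3L, 4L))   # layers x dirs, B, H
  expect_true(all(st$cell == 0.37))
  expect_true(all(buildInitialStates(m, 0, 2)$cell == 0))
  # learnable hidden is identical across the batch
  expect_identical(st$hidden[, 1, ], st$hidden[, 2, ])
  expect_identical(st$hidden[, 1, ], m@params$h0[, 1, ])
})

test_that("the denoiser maps [batch, L] to [batch, L] deterministically", {
  m <- microModel()
  B <- 3; L <- 6
  set.seed(41)
  x <- matrix(rnorm(B * L), B)
  cond <- matrix(sample(1:8, B * L, replace = TRUE), B)
  emb <- embedCondition(m, cond)
  y1 <- denoise(m, x, emb, 0.5)
  y2 <- denoise(m, x, emb, 0.5)
  expect_identical(dim(y1), c(3L, 6L))
  expect_identical(y1, y2)  # evaluation mode is bit-reproducible
  expect_true(all(is.finite(y1)))
  expect_error(denoise(m, x, emb[, 1:3, , drop = FALSE], 0.5), "shape")
})

test_that("output responds to the condition, and not when fully dropped", {
  m <- microModel()
  set.seed(43)
  x <- matrix(rnorm(6), 1)
  condA <- matrix(rep(1L, 6), 1)
  condB <- matrix(rep(2L, 6), 1)
  yA <- denoise(m, x, embedCondition(m, condA), 0.4)
  yB <- denoise(m, x, embedCondition(m, condB), 0.4)
  expect_gt(max(abs(yA - yB)), 0)
  # fully dropped condition (p = 1) erases the dependence
  dA <- withr::with_seed(1, applyConditionDropout(embedCondition(m, condA), 1))
  dB <- withr::with_seed(1, applyConditionDropout(embedCondition(m, condB), 1))
  expect_identical(denoise(m, x, dA, 0.4), denoise(m, x, dB, 0.4))
})

test_that("condition dropout zeroes whole positions at the stated rate", {
  m <- microModel()
  emb <- embedCondition(m, matrix(rep(1L, 6), 1))
  expect_identical(applyConditionDropout(emb, 0)[, , ], emb[, , ])
  expect_true(all(applyConditionDropout(emb, 1) == 0))
  # per-position masking: a position is zeroed across the whole width
  set.seed(55)
  big <- array(1, c(50, 200, 4))
  out <- applyConditionDropout(big, 0.3)
  perPos <- apply(out, c(1, 2), function(v) all(v == 0) || all(v == 1))
  expect_true(all(perPos))
  frac <- mean(apply(out, c(1, 2), function(v) all(v == 0)))
  se <- sqrt(0.3 * 0.7 / (50 * 200))
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("every trainable group receives gradient on a random batch", {
  m <- microModel()
  cfg <- m@config
  set.seed(61)
  x0 <- matrix(runif(2 * 6, -0.9, 0.9), 2)
  cond <- matrix(sample(1:8, 12, replace = TRUE), 2)
  sg <- pepdiff:::trainStepGrads(m@params, cfg, m@schedule, x0, cond)
  gradNorm <- vapply(sg$grads, function(g) {
    s <- 0
    pepdiff:::paramMap(g, function(x) { s <<- s + sum(abs(x)); x })
    s
  }, numeric(1))
  # encoder/decoder LSTMs, embedding, rotary, transformer blocks, fusion,
  # head and the learnable initial hidden all sit on the gradient path
  expect_true(all(gradNorm > 0))
  expect_setequal(names(gradNorm),
                  c("condEmbed", "rope", "condEncoder", "encoderLSTM",
                    "h0", "fusion", "decoderLSTM", "head"))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- microConfig(seqLen = 5L)
  m <- newDenoiser(cfg, cosineSchedule(8), seed = 7)
  set.seed(71)
  B <- 2
  x0 <- matrix(rnorm(B * 5), B)
  xNoised <- 0.5 * x0 + 0.1
  cond <- matrix(sample(0:8, B * 5, replace = TRUE), B)
  nl <- 0.4
  lossOf <- function(params) {
    embF <- pepdiff:::.embedConditionFwd(params, cfg, cond)
    fwd <- pepdiff:::.denoiserFwd(params, cfg, xNoised, embF$y, nl)
    trainingLoss(fwd$y, x0)
  }
  params <- m@params
  embF <- pepdiff:::.embedConditionFwd(params, cfg, cond)
  fwd <- pepdiff:::.denoiserFwd(params, cfg, xNoised, embF$y, nl)
  dY <- 2 * (fwd$y - x0) / length(x0)
  bwd <- pepdiff:::.denoiserBwd(dY, params, cfg, fwd$cache)
  embG <- pepdiff:::.embedConditionBwd(bwd$dCondEmb, params, embF$cache)
  grads <- bwd$grads
  grads$condEmbed <- embG$condEmbed
  grads$rope <- embG$rope
  fp <- pepdiff:::paramFlatten(params)
  fg <- pepdiff:::paramFlatten(grads)
  eps <- 1e-5
  worst <- 0
  for (nm in names(fp)) {
    i <- sample(length(fp[[nm]]), 1)
    p2 <- fp
    p2[[nm]][i] <- p2[[nm]][i] + eps
    lp <- lossOf(pepdiff:::paramUnflatten(p2, params))
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    lm <- lossOf(pepdiff:::paramUnflatten(p2, params))
    num <- (lp - lm) / (2 * eps)
    rel <- abs(num - fg[[nm]][i]) / max(abs(num), abs(fg[[nm]][i]), 1e-6)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-4)
})
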