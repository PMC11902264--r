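test_that("staged subsets are nested, sized and reproducible", {
  ps <- sampleCorpus(defaultGrammar(lengthRange = c(5L, 20L)), 100, seed = 1)
  subs <- stagedSubsets(ps, c(0.25, 0.95), seed = 7)
  expect_identical(vapply(subs, length, integer(1)), c(25L, 95L))
  expect_true(all(sourceIds(subs[[1]]) %in% sourceIds(subs[[2]])))
  subs2 <- stagedSubsets(ps, c(0.25, 0.95), seed = 7)
  expect_identical(sourceIds(subs[[1]]), sourceIds(subs2[[1]]))
  # nesting on random corpora and fraction ladders
  set.seed(17)
  for (r in 1:5) {
    n <- sample(20:80, 1)
    corpus <- sampleCorpus(defaultGrammar(lengthRange = c(5L, 15L)), n, seed = r)
    fr <- sort(runif(3, 0.1, 1))
    subs <- stagedSubsets(corpus, fr, seed = r)
    for (k in 1:2) {
      expect_true(all(sourceIds(subs[[k]]) %in% sourceIds(subs[[k + 1]])))
    }
    expect_identical(vapply(subs, length, integer(1)),
                     pmax(1L, as.integer(round(fr * n))))
  }
  expect_error(stagedSubsets(ps, c(0.5, 0.4), seed = 1), "increasing")
})

test_that("the learning rate decays exponentially onto its endpoint", {
  expect_equal(lrAt(1, 100, 1e-4, 1e-7), 1e-4, tolerance = 1e-15)
  expect_lt(abs(lrAt(100, 100, 1e-4, 1e-7) - 1e-7), 1e-12)
  lrs <- vapply(1:50, lrAt, numeric(1), totalSteps = 50)
  expect_true(all(diff(lrs) < 0))  # monotone decay
  # exponential: constant ratio between consecutive steps
  expect_lt(diff(range(diff(log(lrs)))), 1e-12)
})

test_that("phase training reduces the loss on the deterministic grammar", {
  gram <- deterministicGrammar(lengthRange = c(4L, 10L))
  corpus <- sampleCorpus(gram, 60, seed = 3)
  m <- newDenoiser(microConfig(seqLen = 10L), cosineSchedule(8), seed = 5)
  tc <- trainConfig(lrStart = 3e-3, lrEnd = 1e-3, batchSize = 10L,
                    epochs = 3L, datasetFractions = 1, seed = 6)
  ph <- trainPhase(m, corpus, tc)
  expect_length(ph$epochLoss, 3)
  expect_true(all(diff(ph$epochLoss) < 0))  # strictly decreasing epochs
  expect_length(ph$lossCurve, 3 * 6)
  # identical runs give identical loss curves (all randomness from the seed)
  ph2 <- trainPhase(m, corpus, tc)
  expect_identical(ph$lossCurve, ph2$lossCurve)
  expect_error(trainPhase(m, sampleCorpus(gram, 1, seed = 1)[integer(0)], tc))
})

test_that("fine-tune freezing keeps frozen groups bit-identical", {
  gram <- deterministicGrammar(lengthRange = c(4L, 8L))
  corpus <- sampleCorpus(gram, 20, seed = 8)
  m <- newDenoiser(microConfig(seqLen = 8L), cosineSchedule(8), seed = 9)
  mf <- freezeForFinetune(m)
  expect_setequal(mf@trainable,
                  c("encoderLSTM", "decoderLSTM", "fusion", "head"))
  tc <- trainConfig(lrStart = 1e-3, lrEnd = 5e-4, batchSize = 10L,
                    epochs = 1L, datasetFractions = 1, seed = 10)
  ph <- trainPhase(mf, corpus, tc)
  frozen <- c("condEmbed", "rope", "condEncoder", "h0")
  for (grp in frozen) {
    expect_identical(ph$model@params[[grp]], m@params[[grp]])
  }
  for (grp in mf@trainable) {
    expect_false(identical(ph$model@params[[grp]], m@params[[grp]]))
  }
  # the trainable set receives gradients on a random batch
  set.seed(11)
  enc <- pepdiff:::encodeRecords(corpus, 8L)
  sg <- pepdiff:::trainStepGrads(m@params, m@config, m@schedule,
                                 enc$x0[1:5, ], enc$cond[1:5, ])
  for (grp in mf@trainable) {
    s <- 0
    pepdiff:::paramMap(sg$grads[[grp]], function(x) { s <<- s + sum(abs(x)); x })
    expect_gt(s, 0)
  }
  # unfreezing restores full trainability, idempotently
  expect_setequal(unfreeze(mf)@trainable, names(m@params))
  expect_identical(unfreeze(unfreeze(mf))@trainable, unfreeze(mf)@trainable)
})

test_that("early stopping fires after `patience` non-improving checkpoints", {
  res <- earlyStoppingMonitor(c(0.5, 0.6, 0.55, 0.54), patience = 2)
  expect_true(res$stop)
  expect_identical(res$best, 2L)
  # monotone improvement never stops
  expect_false(earlyStoppingMonitor(seq(0.1, 0.9, by = 0.1), patience = 2)$stop)
  # oracle replay on random score streams
  set.seed(23)
  for (r in 1:20) {
    scores <- runif(sample(3:12, 1))
    patience <- sample(1:4, 1)
    got <- earlyStoppingMonitor(scores, patience)
    sinceBest <- length(scores) - which.max(scores)
    expect_identical(got$stop, sinceBest >= patience)
    expect_identical(got$best, which.max(scores))
  }
})

test_that("checkpoints reproduce generation bit-for-bit", {
  m <- microModel(seed = 31, seqLen = 8L)
  f <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@params, m@params)
  expect_identical(alphaBar(noiseSchedule(m2)), alphaBar(noiseSchedule(m)))
  st <- generationSettings(steps = 8, seed = 77)
  g1 <- generateSequence(m, "HHEE--", st)
  g2 <- generateSequence(m2, "HHEE--", st)
  expect_identical(aaSeqs(g1$record), aaSeqs(g2$record))
  expect_identical(g1$trace, g2$trace)
  # a non-checkpoint file is rejected
  saveRDS(list(a = 1), f)
  expect_error(loadCheckpoint(f), "checkpoint")
})

test_that("the staged pipeline trains, freezes and scores", {
  gram <- deterministicGrammar(lengthRange = c(4L, 8L))
  corpus <- sampleCorpus(gram, 40, seed = 12)
  m <- newDenoiser(microConfig(seqLen = 8L), cosineSchedule(8), seed = 13)
  tc <- trainConfig(lrStart = 2e-3, lrEnd = 1e-3, batchSize = 10L,
                    epochs = 2L, datasetFractions = c(0.5, 0.9), seed = 14,
                    earlyStopPatience = 1L)
  calls <- 0
  fit <- fitDenoiser(m, corpus, tc,
                     scoreFun = function(model) { calls <<- calls + 1; calls })
  expect_true(any(grepl("pretrain", names(fit$history))))
  expect_true(any(grepl("finetune", names(fit$history))))
  expect_length(fit$scores, calls)
  expect_setequal(fit$model@trainable, names(m@params))
})
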