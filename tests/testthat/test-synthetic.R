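test_that("deterministic grammar makes residues a pure function of structure", {
  ps <- sampleCorpus(deterministicGrammar(), 20, seed = 5)
  for (i in seq_len(length(ps))) {
    expect_identical(aaSeqs(ps)[i], detGrammarTarget(ssSeqs(ps)[i]))
  }
})

test_that("corpus sampling is reproducible under a fixed seed", {
  a <- sampleCorpus(defaultGrammar(), 25, seed = 42)
  b <- sampleCorpus(defaultGrammar(), 25, seed = 42)
  expect_identical(a@records, b@records)
  c <- sampleCorpus(defaultGrammar(), 25, seed = 43)
  expect_false(identical(a@records, c@records))
})

test_that("records satisfy the paired-record invariants", {
  ps <- sampleCorpus(defaultGrammar(lengthRange = c(5L, 60L)), 50, seed = 9)
  expect_silent(validObject(ps))
  lens <- ps@records$length
  expect_true(all(lens >= 5 & lens <= 60))
  for (i in seq_len(length(ps))) {
    expect_silent(encodeAA(aaSeqs(ps)[i]))
    expect_silent(encodeSS(ssSeqs(ps)[i]))
  }
})

test_that("empirical emission frequencies match the grammar", {
  gram <- defaultGrammar(lengthRange = c(100L, 250L))
  ps <- sampleCorpus(gram, 60, seed = 77)  # ~10,000 residues
  ss <- strsplit(paste(ssSeqs(ps), collapse = ""), "", fixed = TRUE)[[1]]
  aa <- strsplit(paste(aaSeqs(ps), collapse = ""), "", fixed = TRUE)[[1]]
  expect_gt(length(ss), 10000)
  for (cls in c("H", "E")) {
    emitted <- aa[ss == cls]
    p <- gram@emission[[cls]]
    p <- p[p > 0]
    counts <- table(factor(emitted, levels = names(p)))
    expect_true(all(emitted %in% names(p)))
    chi <- suppressWarnings(stats::chisq.test(counts, p = p))
    expect_gt(chi$p.value, 0.01)
  }
})

test_that("class/residue mutual information matches the analytic value", {
  gram <- defaultGrammar(lengthRange = c(100L, 250L))
  ps <- sampleCorpus(gram, 120, seed = 11)
  ss <- strsplit(paste(ssSeqs(ps), collapse = ""), "", fixed = TRUE)[[1]]
  aa <- strsplit(paste(aaSeqs(ps), collapse = ""), "", fixed = TRUE)[[1]]
  classProbs <- table(ss) / length(ss)
  miExpected <- grammarMutualInformation(gram,
    setNames(as.numeric(classProbs), names(classProbs)))
  joint <- table(ss, aa) / length(ss)
  pS <- rowSums(joint); pA <- colSums(joint)
  miHat <- 0
  for (i in rownames(joint)) for (j in colnames(joint)) {
    if (joint[i, j] > 0) {
      miHat <- miHat + joint[i, j] * log(joint[i, j] / (pS[i] * pA[j]))
    }
  }
  expect_gt(miExpected, 0)  # the learning task is non-degenerate
  expect_lt(abs(miHat - miExpected) / miExpected, 0.1)
})

test_that("capped helix conditions have the stated layout", {
  expect_identical(buildHelixCondition(16), "--HHHHHHHHHHHH--")
  expect_identical(nchar(buildHelixCondition(16)), 16L)
  expect_identical(buildHelixCondition(5), "--H--")
  for (n in c(5, 16, 32, 250)) {
    expect_identical(nchar(buildHelixCondition(n)), as.integer(n))
  }
  expect_error(buildHelixCondition(4), ">= 5")
})

test_that("condition files are validated line by line", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("HH", "EE"), f)
  expect_identical(loadConditionFile(f), c("HH", "EE"))
  writeLines(character(0), f)
  expect_identical(loadConditionFile(f), character(0))
  writeLines("Z", f)
  expect_error(loadConditionFile(f), "line 1")
  writeLines(c("HH", strrep("H", 251)), f)
  expect_error(loadConditionFile(f), "line 2")
})

test_that("condition files round-trip through the writer", {
  f <- withr::local_tempfile(fileext = ".txt")
  conds <- c(buildHelixCondition(16), buildHelixCondition(32), "EEEE--HHH")
  writeConditionFile(conds, f)
  expect_identical(loadConditionFile(f), conds)
  expect_error(writeConditionFile("HHQ", f))
})
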