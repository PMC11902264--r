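test_that("a single-chain fixture yields one paired record", {
  ps <- extractChains(fixturePath("synthetic_helix.pdb"), ssSource = "records")
  expect_identical(length(ps), 1L)
  expect_identical(sourceIds(ps), "synthetic_helix_A")
  expect_identical(nchar(aaSeqs(ps)), nchar(ssSeqs(ps)))
  expect_identical(aaSeqs(ps), "SIAELKARIKELEARM")
  # frozen secondary-structure assignment for the fixture
  expect_identical(ssSeqs(ps), "--HHHHHHHHHHHH--")
  expect_silent(validObject(ps))
})

test_that("a two-chain fixture yields both chains with their ids", {
  ps <- extractChains(fixturePath("synthetic_dimer.pdb"), ssSource = "records")
  expect_identical(length(ps), 2L)
  expect_identical(sourceIds(ps), c("synthetic_dimer_A", "synthetic_dimer_B"))
  expect_identical(ps@records$length, c(12L, 8L))
  # frozen assignments: helix 3-10 on A, strand 2-6 on B
  expect_identical(ssSeqs(ps), c("--HHHHHHHH--", "-EEEEE--"))
})

test_that("extraction failures are explicit", {
  expect_error(extractChains("no_such_file.pdb"), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a structure", bad)
  expect_error(extractChains(bad), basename(bad))
  # requiring the external assigner without the binary names the tool
  if (is.null(pepdiff:::.findDssp())) {
    expect_error(extractChains(fixturePath("synthetic_helix.pdb"),
                               ssSource = "dssp"), "external tool missing")
  }
})

test_that("cleaning deduplicates, validates and length-filters", {
  mk <- function(id, aa, ss) data.frame(sourceId = id, aa = aa, ss = ss,
                                        length = nchar(aa))
  df <- rbind(
    mk("a", "MKVL", "HHHH"),
    mk("b", "MKVL", "EEEE"),              # duplicate aa, collapsed
    mk("c", strrep("A", 251), strrep("H", 251)),  # over the cap
    mk("d", strrep("A", 250), strrep("H", 250)),  # exactly at the cap
    mk("e", "MKXQ", "HHHH"),              # nonstandard residue
    mk("f", "GGGG", "HzHH")               # invalid ss character
  )
  ps <- new("PolypeptideSet", records = df)
  out <- cleanAndFilter(ps)
  expect_identical(sourceIds(out), c("a", "d"))
  # idempotent
  expect_identical(cleanAndFilter(out)@records, out@records)
  # survivors satisfy the record invariants
  expect_silent(validObject(out))
  # independent recount of what must survive a synthetic mixed batch
  set.seed(88)
  aaPool <- c(replicate(20, randomAAString(sample(3:260, 1))), "MKVL", "MKVL")
  df2 <- do.call(rbind, lapply(seq_along(aaPool), function(i) {
    mk(paste0("r", i), aaPool[i], strrep("H", nchar(aaPool[i])))
  }))
  got <- cleanAndFilter(new("PolypeptideSet", records = df2))
  keepMask <- nchar(aaPool) <= 250 & !duplicated(aaPool)
  expect_identical(length(got), sum(keepMask))
  expect_identical(aaSeqs(got), aaPool[keepMask])
})

test_that("corpus statistics are normalized and match hand counts", {
  one <- new("PolypeptideSet", records = data.frame(
    sourceId = "x", aa = "AA", ss = "HH", length = 2L))
  st <- corpusStats(one)
  expect_equal(as.numeric(st$ssClassProportions["H"]), 1)
  expect_equal(as.numeric(st$aaFrequencies["A"]), 1)
  # 5-record toy corpus with a hand count
  toy <- new("PolypeptideSet", records = data.frame(
    sourceId = letters[1:5],
    aa = c("AC", "AC", "GG", "MK", "MA"),
    ss = c("HH", "HE", "--", "TT", "SH"),
    length = rep(2L, 5)))
  st <- corpusStats(toy)
  # residues: A appears 3 of 10 times, C 2, G 2, M 2, K 1
  expect_equal(as.numeric(st$aaFrequencies[c("A", "C", "G", "M", "K")]),
               c(3, 2, 2, 2, 1) / 10)
  expect_equal(as.numeric(st$ssClassProportions[c("H", "E", "-", "T", "S")]),
               c(4, 1, 2, 2, 1) / 10)
  for (d in st[c("lengthHistogram", "ssClassProportions", "aaFrequencies")]) {
    expect_equal(sum(d), 1, tolerance = 1e-9)
  }
  expect_equal(sum(st$pairwiseSSProportionJoint), 1, tolerance = 1e-9)
  expect_error(corpusStats(new("PolypeptideSet", records = one@records[0, ])),
               "empty")
})

test_that("corpora round-trip through the TSV format", {
  ps <- sampleCorpus(defaultGrammar(lengthRange = c(5L, 30L)), 20, seed = 4)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCorpusTSV(ps, f)
  back <- readCorpusTSV(f)
  expect_identical(back@records, ps@records)
  writeLines("wrong\theader", f)
  expect_error(readCorpusTSV(f), "columns")
})
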