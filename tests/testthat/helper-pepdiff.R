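## Shared helpers: random sequence generators, a micro architecture for fast
## pipeline/gradient tests, and the residue map of the deterministic grammar.

randomAAString <- function(n) {
  paste(sample(names(aaAlphabet()), n, replace = TRUE), collapse = "")
}

randomSSString <- function(n) {
  paste(sample(names(ssAlphabet()), n, replace = TRUE), collapse = "")
}

## smallest architecture that still exercises every component
microConfig <- function(seqLen = 6L, condDropoutProb = 0) {
  denoiserConfig(seqLen = seqLen, condVocab = 8L, condEmbedDim = 8L,
                 lstmHidden = 4L, lstmLayers = 2L, attnHeads = 2L,
                 transformerBlocks = 1L, ffDim = 6L, dropout = 0,
                 condDropoutProb = condDropoutProb)
}

microModel <- function(seed = 7L, seqLen = 6L, timesteps = 8L) {
  newDenoiser(microConfig(seqLen = seqLen), cosineSchedule(timesteps),
              seed = seed)
}

## residue emitted by each class under deterministicGrammar()
detGrammarMap <- c(H = "L", E = "V", "-" = "G", T = "P", S = "S", G = "A",
                   B = "I", I = "M")

detGrammarTarget <- function(ss) {
  paste(detGrammarMap[strsplit(ss, "", fixed = TRUE)[[1]]], collapse = "")
}

## fraction of matching positions between two equal-length strings
positionMatchRate <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(ca == cb) / length(ca)
}

fixturePath <- function(name) {
  system.file("extdata", name, package = "pepdiff", mustWork = TRUE)
}
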