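## Evaluation statistics: per-residue concordance between a condition string
## and an observed secondary structure, pairwise percent identity among
## generated sequences, the mean pairwise similarity (with upper-triangle
## heatmaps), the 50-sample diversity protocol, and thin client stubs for
## external folding / homology services.

#' Per-residue concordance
#'
#' The fraction n/N of positions whose observed secondary-structure class
#' matches the condition, where N is the total sequence length.
#'
#' @param conditionSS the condition DSSP string.
#' @param observedSS the observed (structure-derived) DSSP string of equal
#'   length.
#' @return Numeric in [0, 1].
#' @examples
#' perResidueAccuracy("HHHH", "HHEE")  # 0.5
#' @export
perResidueAccuracy <- function(conditionSS, observedSS) {
  if (nchar(conditionSS) != nchar(observedSS)) {
    stop("condition and observed strings must have equal length", call. = FALSE)
  }
  encodeSS(conditionSS); encodeSS(observedSS)  # validate alphabets
  a <- strsplit(conditionSS, "", fixed = TRUE)[[1]]
  b <- strsplit(observedSS, "", fixed = TRUE)[[1]]
  sum(a == b) / length(a)
}

#' Pairwise sequence similarity
#'
#' Percent of identical residues at corresponding positions relative to the
#' total sequence length. Sequences generated under one condition share its
#' length; unequal lengths are an error.
#'
#' @param seqA,seqB residue strings of equal length.
#' @return Percentage in [0, 100].
#' @examples
#' pairwiseSimilarity("AAB", "AAC")  # 66.67
#' @export
pairwiseSimilarity <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  a <- strsplit(seqA, "", fixed = TRUE)[[1]]
  b <- strsplit(seqB, "", fixed = TRUE)[[1]]
  100 * sum(a == b) / length(a)
}

#' Mean pairwise similarity across a set of sequences
#'
#' Computes all n(n-1)/2 upper-triangle pairwise similarities and their mean
#' (the diversity statistic: low values indicate diverse generations). The
#' diagonal (100 by definition) and lower triangle are excluded from the
#' average.
#'
#' @param seqs character vector of >= 2 equal-length residue strings.
#' @return List: \code{savg} (the mean, in percent) and \code{matrix}
#'   (a \code{\linkS4class{SimilarityMatrix}}).
#' @examples
#' averageSimilarity(c("AA", "AA", "CC"))$savg  # mean of 100, 0, 0
#' @export
averageSimilarity <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop("at least 2 sequences are required", call. = FALSE)
  v <- matrix(NA_real_, n, n)
  diag(v) <- 100
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v[i, j] <- pairwiseSimilarity(seqs[i], seqs[j])
    }
  }
  sm <- new("SimilarityMatrix", n = as.integer(n), values = v)
  list(savg = mean(v[upper.tri(v)]), matrix = sm)
}

#' Render an upper-triangle similarity heatmap
#'
#' @param sm a \code{\linkS4class{SimilarityMatrix}}.
#' @param path output PNG path.
#' @return Invisibly, the path.
#' @export
plotSimilarityHeatmap <- function(sm, path) {
  v <- similarityValues(sm)
  diag(v) <- NA  # the diagonal is excluded from the statistic; grey it out
  grDevices::png(path, width = 900, height = 800)
  pheatmap::pheatmap(v, cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = seq(0, 100, length.out = 101),
                     na_col = "grey90", main = "Pairwise sequence similarity (%)")
  grDevices::dev.off()
  invisible(path)
}

#' The k-sample diversity protocol
#'
#' Consecutively generates \code{k} sequences (default 50) under one
#' secondary-structure condition with distinct derived seeds, then reports
#' the full similarity matrix, its upper-triangle mean, the sequences and -
#' when an output prefix is given - FASTA, CSV, JSON and heatmap files.
#'
#' @param model a \code{\linkS4class{PepDenoiser}}.
#' @param condition a DSSP condition string.
#' @param k number of generations (default 50).
#' @param seed run seed; generation i uses a seed derived from it.
#' @param settings base \code{\linkS4class{GenerationSettings}} (its seed is
#'   replaced per generation).
#' @param outPrefix optional path prefix for report files.
#' @return List: \code{sequences}, \code{savg}, \code{matrix}, \code{seeds},
#'   and any written \code{files}.
#' @export
diversityProtocol <- function(model, condition, k = 50L, seed = 1L,
                              settings = generationSettings(),
                              outPrefix = NULL) {
  seeds <- vapply(seq_len(k), function(i) deriveSeed(seed, i), integer(1))
  seqs <- character(k)
  for (i in seq_len(k)) {
    s <- settings
    s@seed <- seeds[i]
    seqs[i] <- aaSeqs(generateSequence(model, condition, s)$record)
  }
  div <- averageSimilarity(seqs)
  files <- character(0)
  if (!is.null(outPrefix)) {
    fa <- paste0(outPrefix, ".fasta")
    writeGenerationsFasta(seqs, condition = condition, seeds = seeds, path = fa)
    csv <- paste0(outPrefix, "_similarity.csv")
    utils::write.csv(similarityValues(div$matrix), csv, row.names = FALSE)
    js <- paste0(outPrefix, "_summary.json")
    jsonlite::write_json(list(condition = condition, k = k,
                              savg = round(div$savg, 2), seeds = seeds),
                         js, auto_unbox = TRUE, digits = NA)
    png <- paste0(outPrefix, "_heatmap.png")
    plotSimilarityHeatmap(div$matrix, png)
    files <- c(fasta = fa, csv = csv, json = js, heatmap = png)
  }
  list(sequences = seqs, savg = div$savg, matrix = div$matrix,
       seeds = seeds, files = files)
}

## ---- external-service client stubs ------------------------------------------

#' External folding / homology service clients
#'
#' Thin clients for a structure-prediction web service and a protein BLAST
#' search. Network access is never required by the package's own analyses:
#' both accept a \code{fixture} path and then simply return the local file,
#' so downstream code (structure parsing, concordance) always consumes local
#' files. Without a fixture and without network permission they fail with an
#' explicit external-service error.
#'
#' @param seq a residue string.
#' @param fixture optional path to a local artifact standing in for the
#'   service response (a PDB file for folding; a tabular hit file for the
#'   homology search).
#' @param offline if TRUE (default), never attempt network access.
#' @return The path to the structure file, or a data.frame of homology hits.
#' @export
esmfoldSubmit <- function(seq, fixture = NULL, offline = TRUE) {
  if (!is.null(fixture)) {
    if (!file.exists(fixture)) stop("fixture file not found", call. = FALSE)
    return(fixture)
  }
  if (offline) {
    stop("external folding service unavailable (offline mode)", call. = FALSE)
  }
  stop("no folding backend configured", call. = FALSE)
}

#' @rdname esmfoldSubmit
#' @export
blastpSubmit <- function(seq, fixture = NULL, offline = TRUE) {
  if (!is.null(fixture)) {
    if (!file.exists(fixture)) stop("fixture file not found", call. = FALSE)
    return(utils::read.delim(fixture, stringsAsFactors = FALSE))
  }
  if (offline) {
    stop("external homology service unavailable (offline mode)", call. = FALSE)
  }
  stop("no homology backend configured", call. = FALSE)
}
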