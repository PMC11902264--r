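## File formats: FASTA for generated sequences, 2-column TSV for corpora,
## plain text for condition strings.

#' Write generated sequences as FASTA
#'
#' One record per generation; headers carry the condition id, the seed and,
#' when available, the per-residue concordance.
#'
#' @param seqs character vector of residue strings.
#' @param condition the condition string (used for the header id).
#' @param seeds integer vector of per-generation seeds (optional).
#' @param apr optional numeric vector of per-residue concordances in [0, 1].
#' @param path output file.
#' @param conditionId short id for the condition (defaults to a digest of
#'   its composition).
#' @return Invisibly, the path.
#' @export
writeGenerationsFasta <- function(seqs, condition, seeds = NULL, apr = NULL,
                                  path, conditionId = NULL) {
  if (is.null(conditionId)) {
    conditionId <- sprintf("cond%dL%s", nchar(condition),
                           substr(gsub("[^HE-]", "x", condition), 1, 6))
  }
  hdr <- vapply(seq_along(seqs), function(i) {
    h <- sprintf("%s_gen%03d", conditionId, i)
    if (!is.null(seeds)) h <- sprintf("%s seed=%d", h, seeds[i])
    if (!is.null(apr) && !is.na(apr[i])) {
      h <- sprintf("%s Apr=%s%%", h, fmtPct(100 * apr[i]))
    }
    h
  }, character(1))
  xs <- Biostrings::AAStringSet(seqs)
  names(xs) <- hdr
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a FASTA file of residue sequences
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
readFastaSequences <- function(path) {
  xs <- Biostrings::readAAStringSet(path)
  setNames(as.character(xs), names(xs))
}

#' Corpus TSV format
#'
#' A corpus is written as a tab-separated file with columns
#' \code{sourceId}, \code{aa} and \code{ss}; \code{readCorpusTSV} restores
#' it as a \code{\linkS4class{PolypeptideSet}}.
#'
#' @param x a \code{\linkS4class{PolypeptideSet}}.
#' @param path file path.
#' @return \code{readCorpusTSV} returns a \code{PolypeptideSet};
#'   \code{writeCorpusTSV} invisibly returns the path.
#' @export
writeCorpusTSV <- function(x, path) {
  utils::write.table(x@records[, c("sourceId", "aa", "ss")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCorpusTSV
#' @export
readCorpusTSV <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sourceId", "aa", "ss")
  if (!all(need %in% names(df))) {
    stop(sprintf("corpus file must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  df$length <- nchar(df$aa)
  new("PolypeptideSet", records = df[, c("sourceId", "aa", "ss", "length")])
}

#' Write condition strings as plain text
#'
#' @param conditions character vector of DSSP condition strings.
#' @param path file path (one condition per line).
#' @return Invisibly, the path.
#' @export
writeConditionFile <- function(conditions, path) {
  for (s in conditions) encodeSS(s)  # validate before writing
  writeLines(conditions, path)
  invisible(path)
}
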