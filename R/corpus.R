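## Real-data corpus path: extract polypeptide chains and per-residue
## secondary structure from macromolecular structure files, clean and
## deduplicate them, and compute corpus statistics.

.findDssp <- function() {
  for (exe in c("mkdssp", "dssp")) {
    p <- Sys.which(exe)
    if (nzchar(p)) return(p)
  }
  NULL
}

## Secondary structure for one chain from the structure file's own
## HELIX/SHEET annotation records: H over helix ranges, E over sheet ranges,
## '-' elsewhere.
.ssFromRecords <- function(pdb, chain, resnos) {
  ss <- rep("-", length(resnos))
  mark <- function(tbl, code) {
    if (is.null(tbl) || length(tbl$chain) == 0) return()
    for (i in seq_along(tbl$chain)) {
      if (tbl$chain[i] != chain) next
      hit <- resnos >= tbl$start[i] & resnos <= tbl$end[i]
      ss[hit] <<- code
    }
  }
  mark(pdb$helix, "H")
  mark(pdb$sheet, "E")
  paste(ss, collapse = "")
}

.ssFromDssp <- function(pdb, chain, resnos, exe) {
  out <- bio3d::dssp(pdb, exefile = exe)
  sse <- out$sse  # named per-residue codes, names like "12_A"
  key <- paste0(resnos, "_", chain)
  codes <- sse[key]
  codes[is.na(codes) | codes == " " | codes == ""] <- "-"
  paste(codes, collapse = "")
}

#' Extract polypeptide chains from a structure file
#'
#' Parses a PDB or mmCIF file, extracts every polypeptide chain in author
#' order as a residue string, and assigns a per-residue DSSP secondary
#' structure string. Secondary structure comes from a DSSP executable
#' (\code{mkdssp}/\code{dssp}) when one is on the PATH, or otherwise from
#' the file's own HELIX/SHEET annotation records (H/E, '-' elsewhere).
#' Chains containing nonstandard residues are dropped entirely, with a
#' message.
#'
#' @param path structure file (.pdb or .cif).
#' @param ssSource "auto" (DSSP if available, else annotation records),
#'   "dssp" (require the external tool) or "records".
#' @return A \code{\linkS4class{PolypeptideSet}}, one record per surviving
#'   chain, with sourceId \code{"<file stem>_<chain>"}.
#' @export
extractChains <- function(path, ssSource = c("auto", "dssp", "records")) {
  ssSource <- match.arg(ssSource)
  if (!file.exists(path)) stop(sprintf("structure file not found: %s", path),
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) {
      stop(sprintf("failed to parse structure file %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    stop(sprintf("failed to parse structure file %s: no atom records", path),
         call. = FALSE)
  }
  exe <- .findDssp()
  if (ssSource == "dssp" && is.null(exe)) {
    stop("external tool missing: no DSSP executable (mkdssp/dssp) on PATH",
         call. = FALSE)
  }
  useDssp <- ssSource == "dssp" || (ssSource == "auto" && !is.null(exe))
  stem <- tools::file_path_sans_ext(basename(path))
  calpha <- pdb$atom[pdb$atom$elety == "CA" & !is.na(pdb$atom$chain), ]
  chains <- unique(calpha$chain)
  recs <- list()
  for (ch in chains) {
    sub <- calpha[calpha$chain == ch, ]
    sub <- sub[!duplicated(sub$resno), ]
    aa1 <- bio3d::aa321(sub$resid)
    if (any(aa1 == "X" | is.na(aa1))) {
      message(sprintf("dropping chain %s of %s: nonstandard residues", ch, stem))
      next
    }
    ss <- if (useDssp) {
      .ssFromDssp(pdb, ch, sub$resno, exe)
    } else {
      .ssFromRecords(pdb, ch, sub$resno)
    }
    if (nchar(ss) != length(aa1)) {
      message(sprintf("dropping chain %s of %s: unassignable residues", ch, stem))
      next
    }
    recs[[length(recs) + 1]] <- data.frame(
      sourceId = paste0(stem, "_", ch), aa = paste(aa1, collapse = ""),
      ss = ss, length = length(aa1), stringsAsFactors = FALSE)
  }
  df <- if (length(recs)) do.call(rbind, recs) else
    data.frame(sourceId = character(0), aa = character(0), ss = character(0),
               length = integer(0))
  new("PolypeptideSet", records = df)
}

#' Clean, deduplicate and length-filter a corpus
#'
#' Collapses exact duplicate amino-acid sequences to their first occurrence,
#' removes records with invalid residue or secondary-structure characters,
#' and removes records longer than \code{maxLen} (250, the model's operating
#' cap). Order is otherwise preserved; the operation is idempotent.
#'
#' @param x a \code{\linkS4class{PolypeptideSet}}.
#' @param maxLen maximum retained length.
#' @return The filtered \code{PolypeptideSet}.
#' @export
cleanAndFilter <- function(x, maxLen = 250L) {
  df <- x@records
  if (nrow(df) == 0) return(x)
  okChars <- vapply(seq_len(nrow(df)), function(i) {
    isTRUE(tryCatch({encodeAA(df$aa[i]); encodeSS(df$ss[i]); TRUE},
                    error = function(e) FALSE))
  }, logical(1))
  df <- df[okChars & df$length <= maxLen & df$length >= 1, , drop = FALSE]
  df <- df[!duplicated(df$aa), , drop = FALSE]
  rownames(df) <- NULL
  new("PolypeptideSet", records = df)
}

#' Corpus statistics
#'
#' Length histogram, secondary-structure class proportions, residue
#' frequencies and the joint distribution across sequences of per-sequence
#' proportional content for a pair of secondary-structure classes
#' (helix/sheet by default). All distributions are normalized to sum to 1.
#'
#' @param x a non-empty \code{\linkS4class{PolypeptideSet}}.
#' @param jointPair the two DSSP classes for the joint proportion table.
#' @param jointBins number of proportion bins per axis.
#' @return List: \code{lengthHistogram}, \code{ssClassProportions},
#'   \code{aaFrequencies}, \code{pairwiseSSProportionJoint}.
#' @export
corpusStats <- function(x, jointPair = c("H", "E"), jointBins = 10L) {
  if (length(x) == 0) stop("corpus is empty", call. = FALSE)
  df <- x@records
  lens <- df$length
  lengthHistogram <- table(factor(lens, levels = seq_len(max(lens))))
  lengthHistogram <- lengthHistogram / sum(lengthHistogram)
  ssAll <- strsplit(paste(df$ss, collapse = ""), "", fixed = TRUE)[[1]]
  ssClassProportions <- table(factor(ssAll, levels = names(ssAlphabet())))
  ssClassProportions <- ssClassProportions / sum(ssClassProportions)
  aaAll <- strsplit(paste(df$aa, collapse = ""), "", fixed = TRUE)[[1]]
  aaFrequencies <- table(factor(aaAll, levels = names(aaAlphabet())))
  aaFrequencies <- aaFrequencies / sum(aaFrequencies)
  propOf <- function(s, cls) {
    cs <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(cs == cls) / length(cs)
  }
  p1 <- vapply(df$ss, propOf, numeric(1), cls = jointPair[1])
  p2 <- vapply(df$ss, propOf, numeric(1), cls = jointPair[2])
  brks <- seq(0, 1, length.out = jointBins + 1)
  joint <- table(cut(p1, brks, include.lowest = TRUE),
                 cut(p2, brks, include.lowest = TRUE))
  joint <- joint / sum(joint)
  list(lengthHistogram = lengthHistogram,
       ssClassProportions = ssClassProportions,
       aaFrequencies = aaFrequencies,
       pairwiseSSProportionJoint = joint)
}

#' Write a corpus statistics report as JSON
#'
#' @param stats output of \code{\link{corpusStats}}.
#' @param path JSON file path.
#' @return Invisibly, the path.
#' @export
writeCorpusStatsJSON <- function(stats, path) {
  obj <- list(
    lengthHistogram = as.list(stats$lengthHistogram),
    ssClassProportions = as.list(stats$ssClassProportions),
    aaFrequencies = as.list(stats$aaFrequencies),
    pairwiseSSProportionJoint = as.data.frame.matrix(stats$pairwiseSSProportionJoint))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
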