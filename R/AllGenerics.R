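#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x an object.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphaBar", function(x) standardGeneric("alphaBar"))

#' @rdname accessors
#' @export
setGeneric("nTimesteps", function(x) standardGeneric("nTimesteps"))

#' @rdname accessors
#' @export
setGeneric("seqValues", function(x) standardGeneric("seqValues"))

#' @rdname accessors
#' @export
setGeneric("trueLength", function(x) standardGeneric("trueLength"))

#' @rdname accessors
#' @export
setGeneric("aaSeqs", function(x) standardGeneric("aaSeqs"))

#' @rdname accessors
#' @export
setGeneric("ssSeqs", function(x) standardGeneric("ssSeqs"))

#' @rdname accessors
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' @rdname accessors
#' @export
setGeneric("similarityValues", function(x) standardGeneric("similarityValues"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("noiseSchedule", function(x) standardGeneric("noiseSchedule"))

setMethod("alphaBar", "NoiseSchedule", function(x) x@alphaBar)
setMethod("nTimesteps", "NoiseSchedule", function(x) x@timesteps)
setMethod("seqValues", "EncodedSequence", function(x) x@values)
setMethod("trueLength", "EncodedSequence", function(x) x@length)
setMethod("aaSeqs", "PolypeptideSet", function(x) x@records$aa)
setMethod("ssSeqs", "PolypeptideSet", function(x) x@records$ss)
setMethod("sourceIds", "PolypeptideSet", function(x) x@records$sourceId)
setMethod("similarityValues", "SimilarityMatrix", function(x) x@values)
setMethod("modelConfig", "PepDenoiser", function(x) x@config)
setMethod("noiseSchedule", "PepDenoiser", function(x) x@schedule)

#' @export
setMethod("length", "PolypeptideSet", function(x) nrow(x@records))

setMethod("show", "NoiseSchedule", function(object) {
  ab <- object@alphaBar
  cat(sprintf("NoiseSchedule: T = %d, alphaBar[T] = %.3g\n",
              object@timesteps, ab[length(ab)]))
})

setMethod("show", "EncodedSequence", function(object) {
  cat(sprintf("EncodedSequence: length %d of %d (K = %d)\n",
              object@length, length(object@values), object@alphabetSize))
})

setMethod("show", "PolypeptideSet", function(object) {
  n <- nrow(object@records)
  cat(sprintf("PolypeptideSet with %d record%s\n", n, if (n == 1) "" else "s"))
  if (n > 0) {
    lens <- object@records$length
    cat(sprintf("  lengths: %d-%d (median %.0f)\n",
                min(lens), max(lens), stats::median(lens)))
    show <- head(object@records, 3)
    for (i in seq_len(nrow(show))) {
      cat(sprintf("  %s  %s...\n", show$sourceId[i],
                  substr(show$aa[i], 1, 24)))
    }
  }
})

setMethod("show", "DenoiserConfig", function(object) {
  cat(sprintf(paste0(
    "DenoiserConfig: seqLen %d, condEmbed %d, lstm %dx%s%d, heads %d, ",
    "blocks %d, ff %d\n"),
    object@seqLen, object@condEmbedDim, object@lstmLayers,
    if (object@bidirectional) "bi-" else "", object@lstmHidden,
    object@attnHeads, object@transformerBlocks, object@ffDim))
})

setMethod("show", "PepDenoiser", function(object) {
  cat("PepDenoiser\n")
  show(object@config)
  show(object@schedule)
  cat(sprintf("  trainable parameters: %s\n",
              format(paramCount(object@params), big.mark = ",")))
  cat(sprintf("  trainable groups: %s\n", paste(object@trainable, collapse = ", ")))
})

setMethod("show", "SimilarityMatrix", function(object) {
  up <- object@values[upper.tri(object@values)]
  cat(sprintf("SimilarityMatrix: %d sequences, %d pairs, mean %.2f%%\n",
              object@n, length(up), mean(up)))
})

setMethod("show", "GrammarSpec", function(object) {
  cat(sprintf("GrammarSpec: lengths %d-%d, segment means H/E %.1f coil %.1f\n",
              object@lengthRange[1], object@lengthRange[2],
              object@segMeanStructured, object@segMeanCoil))
})
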