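## Sequence codec: bidirectional conversion between residue / secondary-
## structure strings and the fixed-length normalized numeric arrays the
## diffusion model operates on.

.SS_CHARS <- c("H", "E", "-", "T", "S", "G", "B", "I")
## Alphabetical one-letter order, A = 1 ... Y = 20. Single point of truth:
## swap here to change the residue codebook.
.AA_CHARS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Secondary-structure and residue codebooks
#'
#' The 8-letter DSSP secondary-structure alphabet (H alpha-helix, E beta-sheet,
#' "-" none, T turn, S bend, G 3-10 helix, B beta-bridge, I pi-helix) coded
#' 1..8, and the 20 standard amino acids coded 1..20 in alphabetical
#' one-letter order. Code 0 is reserved for padding in both alphabets.
#'
#' @return A named integer vector mapping character to code.
#' @examples
#' ssAlphabet()["H"]  # 1
#' aaAlphabet()["A"]  # 1
#' @export
ssAlphabet <- function() setNames(seq_along(.SS_CHARS), .SS_CHARS)

#' @rdname ssAlphabet
#' @export
aaAlphabet <- function() setNames(seq_along(.AA_CHARS), .AA_CHARS)

.encodeWith <- function(x, chars, what) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(integer(0))
  cs <- strsplit(x, "", fixed = TRUE)[[1]]
  codes <- match(cs, chars)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("invalid %s character '%s' at position %d", what, cs[bad], bad),
         call. = FALSE)
  }
  as.integer(codes)
}

#' Encode and decode sequence strings
#'
#' \code{encodeSS}/\code{encodeAA} map a secondary-structure or residue string
#' to integer codes (see \code{\link{ssAlphabet}}); \code{decodeSS}/
#' \code{decodeAA} invert them. Unknown characters (including the ambiguous
#' residues B, J, O, U, X, Z) are rejected with the offending position.
#'
#' @param x a single string over the relevant alphabet.
#' @param codes an integer vector of codes.
#' @return An integer vector of codes, or a string.
#' @examples
#' encodeSS("E-T")   # 2 3 4
#' encodeAA("ACD")   # 1 2 3
#' decodeAA(encodeAA("MKVL"))
#' @export
encodeSS <- function(x) .encodeWith(x, .SS_CHARS, "secondary-structure")

#' @rdname encodeSS
#' @export
encodeAA <- function(x) .encodeWith(x, .AA_CHARS, "residue")

.decodeWith <- function(codes, chars, what) {
  if (length(codes) == 0L) return("")
  if (any(codes < 1L | codes > length(chars))) {
    stop(sprintf("invalid %s code outside 1..%d", what, length(chars)), call. = FALSE)
  }
  paste(chars[codes], collapse = "")
}

#' @rdname encodeSS
#' @export
decodeSS <- function(codes) .decodeWith(codes, .SS_CHARS, "secondary-structure")

#' @rdname encodeSS
#' @export
decodeAA <- function(codes) .decodeWith(codes, .AA_CHARS, "residue")

#' Normalized values of an integer code alphabet
#'
#' Codes 1..K map linearly into (-1, 1) by
#' \eqn{v = (c - (K+1)/2) / ((K-1)/2 + 1)}. For even K no code maps to 0, so
#' 0 unambiguously denotes padding.
#'
#' @param K alphabet size.
#' @return Numeric vector of the K normalized values, in code order.
#' @export
normalizedCodeValues <- function(K) {
  (seq_len(K) - (K + 1) / 2) / ((K - 1) / 2 + 1)
}

#' Normalize codes and pad to the model length
#'
#' Maps integer codes into (-1, 1) and right-pads with zeros to a uniform
#' length of \code{maxLen} (250), the fixed operating width of the diffusion
#' model.
#'
#' @param codes integer codes in 1..K.
#' @param K alphabet size (20 for residues).
#' @param maxLen padded length cap; inputs longer than this are rejected.
#' @return An \code{\linkS4class{EncodedSequence}}.
#' @examples
#' es <- normalizeAndPad(encodeAA("ACD"), 20)
#' trueLength(es)      # 3
#' seqValues(es)[1:4]  # three normalized values then 0
#' @export
normalizeAndPad <- function(codes, K = 20L, maxLen = 250L) {
  n <- length(codes)
  if (n < 1L) stop("codes must be non-empty", call. = FALSE)
  if (n > maxLen) {
    stop(sprintf("sequence of length %d exceeds the %d-residue cap", n, maxLen),
         call. = FALSE)
  }
  if (any(codes < 1L | codes > K)) stop("codes must lie in 1..K", call. = FALSE)
  v <- numeric(maxLen)
  v[seq_len(n)] <- normalizedCodeValues(K)[codes]
  new("EncodedSequence", values = v, length = as.integer(n),
      alphabetSize = as.integer(K))
}

#' Map continuous values back to integer codes
#'
#' Inverts the normalization by nearest normalized code value over the first
#' \code{length} positions; ties at the midpoint between adjacent codes break
#' toward the lower code, and values beyond the extreme codes clamp to code 1
#' or K. Total on the reals, so raw denoiser output can always be quantized.
#'
#' @param values numeric vector (at least \code{length} entries).
#' @param K alphabet size.
#' @param length number of leading positions to quantize.
#' @return Integer codes of length \code{length}.
#' @examples
#' quantizeValues(normalizedCodeValues(20)[c(3, 7)], 20, 2)  # 3 7
#' @export
quantizeValues <- function(values, K = 20L, length = base::length(values)) {
  if (length > base::length(values)) {
    stop("length exceeds the number of supplied values", call. = FALSE)
  }
  v <- values[seq_len(length)]
  scaled <- v * ((K - 1) / 2 + 1) + (K + 1) / 2
  # midpoint ties go to the lower code; the 1e-9 guard keeps exact ties below
  # the boundary despite floating-point round-off in the scaling
  codes <- as.integer(ceiling(scaled - 0.5 - 1e-9))
  pmax(1L, pmin(as.integer(K), codes))
}
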