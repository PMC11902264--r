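#' @importFrom stats rnorm runif setNames
#' @importFrom utils head modifyList
NULL

## Seed derivation: one run seed deterministically spawns per-component seeds.
## Simple 32-bit mixing keeps every derived seed a valid R integer.
deriveSeed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  saltNum <- if (is.character(salt)) {
    sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  } else {
    as.numeric(salt)
  }
  x <- (as.numeric(seed) * 2654435761 + saltNum * 40503 + 97) %% 2147483647
  as.integer(x)
}

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## ---- nested parameter-list helpers -----------------------------------------
## Model parameters live in nested named lists whose leaves are numeric
## arrays. These helpers map/zip over leaves while preserving structure.

paramMap <- function(params, f) {
  if (is.list(params)) {
    out <- lapply(params, paramMap, f = f)
    attributes(out) <- attributes(params)
    out
  } else {
    f(params)
  }
}

paramZip <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- mapply(paramZip, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    attributes(out) <- attributes(a)
    out
  } else {
    f(a, b)
  }
}

## Flatten to a named list of leaves; names are slash-separated paths.
paramFlatten <- function(params, prefix = "") {
  if (!is.list(params)) {
    return(setNames(list(params), prefix))
  }
  out <- list()
  nms <- names(params)
  if (is.null(nms)) nms <- as.character(seq_along(params))
  for (i in seq_along(params)) {
    path <- if (nzchar(prefix)) paste0(prefix, "/", nms[i]) else nms[i]
    out <- c(out, paramFlatten(params[[i]], path))
  }
  out
}

## Rebuild a nested structure from a flat named list, using `template` for shape.
paramUnflatten <- function(flat, template) {
  rebuild <- function(tmpl, prefix) {
    if (!is.list(tmpl)) {
      leaf <- flat[[prefix]]
      stopifnot(!is.null(leaf))
      return(leaf)
    }
    nms <- names(tmpl)
    if (is.null(nms)) nms <- as.character(seq_along(tmpl))
    out <- vector("list", length(tmpl))
    names(out) <- names(tmpl)
    for (i in seq_along(tmpl)) {
      path <- if (nzchar(prefix)) paste0(prefix, "/", nms[i]) else nms[i]
      out[[i]] <- rebuild(tmpl[[i]], path)
    }
    out
  }
  rebuild(template, "")
}

paramCount <- function(params) {
  total <- 0
  paramMap(params, function(x) {
    total <<- total + length(x)
    x
  })
  total
}

## Sum of squares over all leaves (diagnostics).
paramSumSq <- function(params) {
  total <- 0
  paramMap(params, function(x) {
    total <<- total + sum(x^2)
    x
  })
  total
}

zerosLike <- function(params) paramMap(params, function(x) array(0, dim = if (is.null(dim(x))) length(x) else dim(x)))

fmtPct <- function(x) sprintf("%.2f", round(x, 2))

#' @useDynLib pepdiff, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL
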