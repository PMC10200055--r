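#' @include AllClasses.R AllGenerics.R
NULL

## Atom-wise token grammar: bracket atoms are atomic, the two-letter
## organic-subset halogens are digraphs, %nn is a two-digit ring closure,
## everything else is a single character. Order matters: earlier
## alternatives win.
.SMILES_TOKEN_RE <- "\\[[^][]*\\]|Br|Cl|%[0-9]{2}|[^[:space:]]"

.scanTokens <- function(x, what) {
  if (length(x) != 1L || is.na(x))
    stop(what, " input must be a single string", call. = FALSE)
  if (!nzchar(x))
    stop("empty ", what, " string", call. = FALSE)
  m <- gregexpr(.SMILES_TOKEN_RE, x, perl = TRUE)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (paste(toks, collapse = "") != x)
    stop("malformed ", what, " string: cannot tokenize '", x, "' losslessly",
         call. = FALSE)
  # a '[' surviving as a single-character token means its ']' never came
  bad <- which(toks == "[")
  if (length(bad)) {
    off <- if (bad[1L] == 1L) 1L else
      sum(nchar(toks[seq_len(bad[1L] - 1L)])) + 1L
    stop("malformed ", what, " string '", x,
         "': unclosed '[' at offset ", off, call. = FALSE)
  }
  bad <- which(toks == "]")
  if (length(bad)) {
    off <- if (bad[1L] == 1L) 1L else
      sum(nchar(toks[seq_len(bad[1L] - 1L)])) + 1L
    stop("malformed ", what, " string '", x,
         "': unmatched ']' at offset ", off, call. = FALSE)
  }
  toks
}

#' Tokenize a SMILES string atom-wise
#'
#' Splits a SMILES string into atom-wise tokens: bracket atoms
#' (\code{[C@@H]}, \code{[nH]}, ...) are single tokens, the organic-subset
#' halogens \code{Cl} and \code{Br} are single tokens, \code{\%nn} two-digit
#' ring closures are single tokens, and every other character (aromatic
#' atoms, single-letter elements, bond symbols, parentheses, ring digits,
#' dots) is one token. The split is lossless: the tokens concatenate back
#' to the input.
#'
#' @param smiles a single non-empty SMILES string
#' @return A \linkS4class{TokenSequence} with \code{notation = "SMILES"}.
#' @export
#' @examples
#' tokens(tokenizeSmiles("[C@@H](Br)Cl"))  # 5 tokens
tokenizeSmiles <- function(smiles) {
  new("TokenSequence", notation = "SMILES", sourceString = smiles,
      tokens = .scanTokens(smiles, "SMILES"))
}

#' Tokenize a SMARTS pattern
#'
#' Same grammar as [tokenizeSmiles()], with the SMARTS logical operators
#' (\code{&}, \code{;}, \code{,}, \code{!}) and recursive-SMARTS characters
#' falling through as single-character tokens. Bracket expressions such as
#' \code{[C,N]} stay atomic. Lossless.
#'
#' @param smarts a single non-empty SMARTS string
#' @return A \linkS4class{TokenSequence} with \code{notation = "SMARTS"}.
#' @export
#' @examples
#' tokens(tokenizeSmarts("[C,N]O"))
tokenizeSmarts <- function(smarts) {
  new("TokenSequence", notation = "SMARTS", sourceString = smarts,
      tokens = .scanTokens(smarts, "SMARTS"))
}

#' Tokenize an InChIKey character-wise
#'
#' One token per character, hyphens included. Any non-empty string is
#' accepted; the standard InChIKey layout is 14-10-1 characters.
#'
#' @param inchikey a single non-empty string
#' @return A \linkS4class{TokenSequence} with \code{notation = "INCHIKEY"}.
#' @export
#' @examples
#' tokenizeInchikey("LFQSCWFLJHTTHZ-UHFFFAOYSA-N")
tokenizeInchikey <- function(inchikey) {
  if (length(inchikey) != 1L || is.na(inchikey))
    stop("InChIKey input must be a single string", call. = FALSE)
  if (!nzchar(inchikey)) stop("empty InChIKey string", call. = FALSE)
  new("TokenSequence", notation = "INCHIKEY", sourceString = inchikey,
      tokens = strsplit(inchikey, "", fixed = TRUE)[[1]])
}

#' @rdname sef-accessors
setMethod("tokens", "TokenSequence", function(x) x@tokens)

#' @rdname sef-accessors
setMethod("sourceString", "TokenSequence", function(x) x@sourceString)

#' @rdname sef-accessors
setMethod("notation", "TokenSequence", function(x) x@notation)

setMethod("length", "TokenSequence", function(x) length(x@tokens))

setMethod("show", "TokenSequence", function(object) {
  cat("TokenSequence (", object@notation, "): ",
      length(object@tokens), " tokens\n  ", sep = "")
  cat(paste(object@tokens, collapse = " | "), "\n")
})
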