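#' @include AllClasses.R
NULL

#' Accessors for SEF objects
#'
#' Small accessor generics used across the package's S4 classes:
#' \code{tokens()} and \code{sourceString()} for \linkS4class{TokenSequence},
#' \code{counts()}, \code{totalCount()} and \code{uniqueCount()} for
#' \linkS4class{FrequencyTable}, \code{perAtom()}, \code{paddedValues()} and
#' \code{atomSpecies()} for \linkS4class{FractionalEntropyProfile},
#' \code{bondFrequencies()}, \code{bondCounts()} and \code{entropyBits()} for
#' \linkS4class{BondProfile}, and \code{featureNames()} for
#' \linkS4class{DescriptorMatrix}.
#'
#' @param x an object of the relevant class
#' @return The slot content: a character vector of tokens, a named integer
#'   count vector, scalar totals, numeric entropy values in bits, or a
#'   character vector of feature names, depending on the accessor.
#' @name sef-accessors
#' @aliases tokens sourceString notation counts totalCount uniqueCount
#'   perAtom paddedValues atomSpecies bondFrequencies bondCounts entropyBits
#'   featureNames
#' @examples
#' ts <- tokenizeSmiles("CCO")
#' tokens(ts)
#' ft <- tokenFrequencies(ts)
#' counts(ft)
NULL

#' @rdname sef-accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname sef-accessors
#' @export
setGeneric("sourceString", function(x) standardGeneric("sourceString"))

#' @rdname sef-accessors
#' @export
setGeneric("notation", function(x) standardGeneric("notation"))

#' @rdname sef-accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname sef-accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname sef-accessors
#' @export
setGeneric("uniqueCount", function(x) standardGeneric("uniqueCount"))

#' @rdname sef-accessors
#' @export
setGeneric("perAtom", function(x) standardGeneric("perAtom"))

#' @rdname sef-accessors
#' @export
setGeneric("paddedValues", function(x) standardGeneric("paddedValues"))

#' @rdname sef-accessors
#' @export
setGeneric("atomSpecies", function(x, ...) standardGeneric("atomSpecies"))

#' @rdname sef-accessors
#' @export
setGeneric("bondFrequencies", function(x) standardGeneric("bondFrequencies"))

#' @rdname sef-accessors
#' @export
setGeneric("bondCounts", function(x) standardGeneric("bondCounts"))

#' @rdname sef-accessors
#' @export
setGeneric("entropyBits", function(x) standardGeneric("entropyBits"))

#' @rdname sef-accessors
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Token frequency tables
#'
#' Count the occurrences of each distinct token in a token sequence (or a
#' plain character vector of tokens), producing the
#' \linkS4class{FrequencyTable} from which Shannon entropies are computed.
#' The result depends only on the token multiset, not on token order.
#'
#' @param x a \linkS4class{TokenSequence} or a character vector of tokens
#' @return A \linkS4class{FrequencyTable}.
#' @export
#' @examples
#' tokenFrequencies(c("C", "C", "O"))
setGeneric("tokenFrequencies", function(x) standardGeneric("tokenFrequencies"))

#' Shannon entropy of a token frequency distribution
#'
#' Computes \eqn{S = -\sum_i f_i \log_2 f_i} over the relative frequencies
#' \eqn{f_i = n_i / N} of the distinct items in a frequency table, in bits.
#' Zero-count items contribute nothing (the \eqn{0 \log 0 := 0} convention),
#' and a table with a single distinct item returns exactly 0. Frequencies
#' are formed as exact integer ratios before the logarithm is taken.
#'
#' @param x a \linkS4class{FrequencyTable}, a \linkS4class{TokenSequence}
#'   (its frequencies are formed first), or a character vector of tokens
#' @return Entropy in bits (non-negative numeric scalar, at most
#'   \eqn{\log_2 k} for \eqn{k} distinct items).
#' @seealso [smilesEntropy()], [inchikeyEntropy()], [smartsEntropy()]
#' @export
#' @examples
#' shannonEntropy(tokenizeSmiles("CCO"))   # 0.9182958
#' shannonEntropy(c("A", "A"))             # exactly 0
setGeneric("shannonEntropy", function(x) standardGeneric("shannonEntropy"))
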