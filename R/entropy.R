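#' @include parse.R
NULL

.freqTable <- function(items) {
  tb <- table(items)
  counts <- as.integer(tb)
  names(counts) <- names(tb)
  new("FrequencyTable", counts = counts,
      total = sum(counts), unique = sum(counts > 0L))
}

#' @rdname tokenFrequencies
setMethod("tokenFrequencies", "TokenSequence", function(x) {
  if (length(x@tokens) == 0L)
    stop("empty token sequence", call. = FALSE)
  .freqTable(x@tokens)
})

#' @rdname tokenFrequencies
setMethod("tokenFrequencies", "character", function(x) {
  if (length(x) == 0L) stop("empty token sequence", call. = FALSE)
  .freqTable(x)
})

#' @rdname sef-accessors
setMethod("counts", "FrequencyTable", function(x) x@counts)

#' @rdname sef-accessors
setMethod("totalCount", "FrequencyTable", function(x) x@total)

#' @rdname sef-accessors
setMethod("uniqueCount", "FrequencyTable", function(x) x@unique)

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable: N =", object@total, ", k =", object@unique, "\n")
  print(object@counts)
})

## -sum(f log2 f) with exact integer ratios; 0 log 0 := 0; exactly 0 for a
## single distinct item.
.entropyFromCounts <- function(counts, total) {
  counts <- counts[counts > 0L]
  if (length(counts) <= 1L) return(0)
  f <- counts / total
  -sum(f * log2(f))
}

#' @rdname shannonEntropy
setMethod("shannonEntropy", "FrequencyTable", function(x) {
  if (x@total == 0L) stop("empty frequency table", call. = FALSE)
  val <- .entropyFromCounts(x@counts, x@total)
  attr(val, "k") <- x@unique
  val
})

#' @rdname shannonEntropy
setMethod("shannonEntropy", "TokenSequence", function(x) {
  val <- shannonEntropy(tokenFrequencies(x))
  attr(val, "notation") <- x@notation
  val
})

#' @rdname shannonEntropy
setMethod("shannonEntropy", "character", function(x) {
  shannonEntropy(tokenFrequencies(x))
})

#' Scalar string entropies of a molecule
#'
#' Convenience wrappers composing the tokenizer and [shannonEntropy()]:
#' \code{smilesEntropy()} tokenizes atom-wise, \code{smartsEntropy()}
#' transliterates the SMILES to a SMARTS pattern (unless a SMARTS string is
#' supplied directly via \code{fromSmiles = FALSE}) and tokenizes that, and
#' \code{inchikeyEntropy()} tokenizes an InChIKey character-wise. All are
#' vectorized over their first argument and return bits.
#'
#' @param smiles,smarts,inchikey character vectors of the respective strings
#' @param fromSmiles for \code{smartsEntropy()}: treat the input as SMILES
#'   and transliterate with [smilesToSmarts()] first (default TRUE)
#' @return Numeric vector of entropies in bits.
#' @export
#' @examples
#' smilesEntropy("CCO")  # 0.9182958
smilesEntropy <- function(smiles) {
  vapply(smiles, function(s) as.numeric(shannonEntropy(tokenizeSmiles(s))),
         numeric(1), USE.NAMES = FALSE)
}

#' @rdname smilesEntropy
#' @export
smartsEntropy <- function(smarts, fromSmiles = TRUE) {
  vapply(smarts, function(s) {
    pat <- if (fromSmiles) smilesToSmarts(s) else s
    as.numeric(shannonEntropy(tokenizeSmarts(pat)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname smilesEntropy
#' @export
inchikeyEntropy <- function(inchikey) {
  vapply(inchikey,
         function(s) as.numeric(shannonEntropy(tokenizeInchikey(s))),
         numeric(1), USE.NAMES = FALSE)
}

#' Fractional Shannon entropy profile of a molecule
#'
#' Apportions a molecule's total string entropy \eqn{S_m} over its atoms,
#' analogously to the partial pressure of a component in a gas mixture:
#' each atom of species j carries \eqn{s_j = f_j S_m}, where \eqn{f_j} is
#' the number of atoms of species j divided by the total number of counted
#' atoms. All atoms of one species share one value, and the values summed
#' over distinct species recover \eqn{S_m} exactly.
#'
#' By default \code{totalEntropy} is the molecule's SMILES entropy; any
#' other scalar entropy (for example an InChIKey entropy) may be supplied,
#' since the apportioning rule is agnostic of where \eqn{S_m} came from.
#'
#' @param smiles a SMILES string (or \linkS4class{Molecule})
#' @param totalEntropy the total entropy to apportion, bits; default
#'   \code{smilesEntropy(smiles)}
#' @param hydrogens hydrogen-counting mode, see [atomSpecies()]
#' @return An unpadded \linkS4class{FractionalEntropyProfile}.
#' @seealso [padProfile()]
#' @export
#' @examples
#' p <- fractionalEntropy("CCO")
#' perAtom(p)   # 0.612, 0.612, 0.306
fractionalEntropy <- function(smiles, totalEntropy = NULL,
                              hydrogens = c("explicit", "all")) {
  hydrogens <- match.arg(hydrogens)
  mol <- if (is(smiles, "Molecule")) smiles else parseSmiles(smiles)
  if (is.null(totalEntropy)) totalEntropy <- smilesEntropy(mol@smiles)
  species <- atomSpecies(mol, hydrogens = hydrogens)
  m <- length(species)
  if (m == 0L)
    stop("degenerate molecule: no counted atoms in '", mol@smiles, "'",
         call. = FALSE)
  ft <- .freqTable(species)
  fractions <- ft@counts / ft@total
  perAtom <- as.numeric(totalEntropy) * unname(fractions[species])
  new("FractionalEntropyProfile", smiles = mol@smiles,
      atomSpecies = species, perAtom = perAtom,
      totalEntropy = as.numeric(totalEntropy),
      padded = numeric(0), nMax = NA_integer_)
}

#' Zero-pad a fractional entropy profile to a fixed width
#'
#' Pads the per-atom vector with zeros, \eqn{(N - m)/2} on each side for a
#' molecule of m atoms and target width N. When \eqn{N - m} is odd the
#' extra zero goes on the right (floor left, ceiling right), a fixed
#' convention that keeps batches reproducible. The padded vector conserves
#' the per-atom sum exactly.
#'
#' @param profile a \linkS4class{FractionalEntropyProfile}
#' @param nMax target width; must be at least the profile's atom count
#' @return The profile with its \code{padded} slot filled.
#' @export
#' @examples
#' p <- padProfile(fractionalEntropy("CCO"), 7)
#' paddedValues(p)
padProfile <- function(profile, nMax) {
  stopifnot(is(profile, "FractionalEntropyProfile"))
  m <- length(profile@perAtom)
  nMax <- as.integer(nMax)
  if (nMax < m)
    stop("padding capacity error: molecule has ", m,
         " atoms but nMax is ", nMax, call. = FALSE)
  left <- (nMax - m) %/% 2L
  right <- nMax - m - left
  profile@padded <- c(numeric(left), profile@perAtom, numeric(right))
  profile@nMax <- nMax
  validObject(profile)
  profile
}

#' @rdname sef-accessors
setMethod("perAtom", "FractionalEntropyProfile", function(x) x@perAtom)

#' @rdname sef-accessors
setMethod("paddedValues", "FractionalEntropyProfile", function(x) x@padded)

#' @rdname sef-accessors
setMethod("atomSpecies", "FractionalEntropyProfile",
          function(x, ...) x@atomSpecies)

setMethod("show", "FractionalEntropyProfile", function(object) {
  cat("FractionalEntropyProfile:", object@smiles, "\n")
  cat("  S_m =", format(object@totalEntropy, digits = 7), "bits over",
      length(object@perAtom), "atoms\n")
  v <- round(object@perAtom, 4)
  cat("  ", paste(object@atomSpecies, v, sep = "=", collapse = " "), "\n")
  if (length(object@padded))
    cat("  padded to width", object@nMax, "\n")
})

#' Bond-type frequency profile and bond entropy of a molecule
#'
#' Counts the molecule's bonds over the fixed, ordered bond-type vocabulary
#' SINGLE, DOUBLE, TRIPLE, QUADRUPLE, AROMATIC, HYDROGEN, IONIC (the bonds
#' as written in the SMILES string, see [parseSmiles()]), converts the
#' counts to frequencies, and reduces them to the Shannon entropy of bonds
#' \eqn{S_{bf} = -\sum_i f_i \log_2 f_i} in bits. A molecule with at most
#' one bond type present has bond entropy exactly 0; a molecule with no
#' bonds has an all-zero frequency vector.
#'
#' @param smiles a SMILES string or \linkS4class{Molecule}
#' @return A \linkS4class{BondProfile}.
#' @export
#' @examples
#' bondProfile("C=CC")   # 0.5 / 0.5 over SINGLE and DOUBLE, 1 bit
bondProfile <- function(smiles) {
  mol <- if (is(smiles, "Molecule")) smiles else parseSmiles(smiles)
  types <- mol@bonds$type
  unknown <- setdiff(unique(types), .BOND_TYPES)
  if (length(unknown))
    stop("unknown bond type(s) in '", mol@smiles, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cnt <- vapply(.BOND_TYPES, function(tp) sum(types == tp), integer(1))
  tot <- sum(cnt)
  freq <- if (tot > 0L) cnt / tot else rep(0, 7L)
  ent <- if (tot > 0L) .entropyFromCounts(cnt, tot) else 0
  new("BondProfile", smiles = mol@smiles, bondTypes = .BOND_TYPES,
      counts = cnt, frequencies = unname(freq), entropyBits = ent)
}

#' @rdname sef-accessors
setMethod("bondFrequencies", "BondProfile", function(x) {
  stats::setNames(x@frequencies, x@bondTypes)
})

#' @rdname sef-accessors
setMethod("bondCounts", "BondProfile", function(x) {
  stats::setNames(x@counts, x@bondTypes)
})

#' @rdname sef-accessors
setMethod("entropyBits", "BondProfile", function(x) x@entropyBits)

setMethod("show", "BondProfile", function(object) {
  cat("BondProfile:", object@smiles, "\n")
  pos <- object@counts > 0L
  if (any(pos)) {
    cat("  ", paste(object@bondTypes[pos], object@counts[pos],
                    sep = ":", collapse = " "), "\n")
  } else cat("  (no bonds)\n")
  cat("  S_bf =", format(object@entropyBits, digits = 7), "bits\n")
})
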