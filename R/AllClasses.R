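.NOTATIONS <- c("SMILES", "SMARTS", "INCHIKEY", "BONDS")

## Fixed bond-type vocabulary, in its defined order. SMILES-derived graphs
## only ever populate the first five; HYDROGEN and IONIC are retained so the
## bond block has a stable width across datasets.
.BOND_TYPES <- c("SINGLE", "DOUBLE", "TRIPLE", "QUADRUPLE",
                 "AROMATIC", "HYDROGEN", "IONIC")

#' TokenSequence: ordered tokens of one string representation
#'
#' The ordered tokens extracted from one molecular string (SMILES, SMARTS or
#' InChIKey), together with the source string and the notation it came from.
#' Tokenization is lossless: concatenating the tokens in order reproduces
#' the source string exactly, which the class validity enforces.
#'
#' @slot notation one of \code{"SMILES"}, \code{"SMARTS"}, \code{"INCHIKEY"}
#' @slot sourceString the input string
#' @slot tokens character vector of tokens, in order
#' @seealso [tokenizeSmiles()], [tokenizeSmarts()], [tokenizeInchikey()]
#' @exportClass TokenSequence
setClass("TokenSequence",
         representation(notation = "character",
                        sourceString = "character",
                        tokens = "character"))

setValidity("TokenSequence", function(object) {
  msg <- NULL
  if (length(object@notation) != 1L || !object@notation %in% .NOTATIONS)
    msg <- c(msg, "notation must be one of SMILES, SMARTS, INCHIKEY")
  if (paste(object@tokens, collapse = "") != object@sourceString)
    msg <- c(msg, "tokens do not concatenate back to sourceString")
  if (nzchar(object@sourceString) && length(object@tokens) == 0L)
    msg <- c(msg, "non-empty source must yield at least one token")
  if (is.null(msg)) TRUE else msg
})

#' FrequencyTable: occurrence counts of tokens, atoms or bond types
#'
#' A map from item (token, element symbol or bond type) to its occurrence
#' count, with the total count N and the number of distinct items k. The
#' relative frequencies \eqn{f_i = n_i/N} sum to one whenever N > 0.
#'
#' @slot counts named integer vector of positive occurrence counts
#' @slot total integer, sum of counts (N)
#' @slot unique integer, number of distinct items with positive count (k)
#' @seealso [tokenFrequencies()], [atomFrequencies()], [shannonEntropy()]
#' @exportClass FrequencyTable
setClass("FrequencyTable",
         representation(counts = "integer",
                        total = "integer",
                        unique = "integer"))

setValidity("FrequencyTable", function(object) {
  msg <- NULL
  if (is.null(names(object@counts)) && length(object@counts) > 0L)
    msg <- c(msg, "counts must be named")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (sum(object@counts) != object@total)
    msg <- c(msg, "total must equal sum(counts)")
  if (sum(object@counts > 0L) != object@unique)
    msg <- c(msg, "unique must equal the number of positive counts")
  if (is.null(msg)) TRUE else msg
})

#' FractionalEntropyProfile: per-atom entropy values of one molecule
#'
#' The molecule's total string entropy \eqn{S_m} apportioned to its atoms by
#' atom-count fraction, analogously to partial pressures in a gas mixture:
#' every atom of species j carries \eqn{s_j = f_j S_m} where \eqn{f_j} is
#' the fraction of counted atoms belonging to species j. The profile
#' optionally carries a zero-padded fixed-length copy so molecules of
#' different sizes can share one descriptor block.
#'
#' @slot smiles the SMILES the atoms were read from
#' @slot atomSpecies element symbols atom-by-atom, in occurrence order
#' @slot perAtom per-atom entropy values in bits, aligned with atomSpecies
#' @slot totalEntropy the total entropy \eqn{S_m} that was apportioned
#' @slot padded zero-padded vector of length \code{nMax} (length 0 until
#'   [padProfile()] is applied)
#' @slot nMax target padded width (NA until padded)
#' @seealso [fractionalEntropy()], [padProfile()]
#' @exportClass FractionalEntropyProfile
setClass("FractionalEntropyProfile",
         representation(smiles = "character",
                        atomSpecies = "character",
                        perAtom = "numeric",
                        totalEntropy = "numeric",
                        padded = "numeric",
                        nMax = "integer"))

setValidity("FractionalEntropyProfile", function(object) {
  msg <- NULL
  if (length(object@perAtom) != length(object@atomSpecies))
    msg <- c(msg, "perAtom and atomSpecies lengths differ")
  if (any(object@perAtom < 0))
    msg <- c(msg, "per-atom entropies must be non-negative")
  sp <- split(object@perAtom, object@atomSpecies)
  if (!all(vapply(sp, function(v) length(unique(v)) == 1L, logical(1))))
    msg <- c(msg, "atoms of one species must share one value")
  if (length(object@padded) > 0L) {
    if (is.na(object@nMax) || length(object@padded) != object@nMax)
      msg <- c(msg, "padded length must equal nMax")
    if (sum(object@padded) != sum(object@perAtom))
      msg <- c(msg, "padding must conserve the per-atom sum")
  }
  if (is.null(msg)) TRUE else msg
})

#' BondProfile: bond-type frequencies and bond entropy of one molecule
#'
#' Occurrence frequencies over the fixed, ordered bond-type vocabulary
#' (SINGLE, DOUBLE, TRIPLE, QUADRUPLE, AROMATIC, HYDROGEN, IONIC) and the
#' Shannon entropy of that frequency distribution, in bits. Frequencies sum
#' to one when the molecule has at least one bond and are all zero
#' otherwise; the entropy is zero exactly when at most one bond type occurs.
#'
#' @slot smiles the SMILES the bonds were read from
#' @slot bondTypes the fixed bond-type vocabulary, in order
#' @slot counts integer occurrence counts aligned with bondTypes
#' @slot frequencies relative frequencies aligned with bondTypes
#' @slot entropyBits Shannon entropy of the bond frequencies, bits
#' @seealso [bondProfile()]
#' @exportClass BondProfile
setClass("BondProfile",
         representation(smiles = "character",
                        bondTypes = "character",
                        counts = "integer",
                        frequencies = "numeric",
                        entropyBits = "numeric"))

setValidity("BondProfile", function(object) {
  msg <- NULL
  if (!identical(object@bondTypes, .BOND_TYPES))
    msg <- c(msg, "bondTypes must be the fixed 7-type vocabulary")
  if (length(object@frequencies) != 7L || length(object@counts) != 7L)
    msg <- c(msg, "counts and frequencies must have length 7")
  if (any(object@frequencies < 0))
    msg <- c(msg, "frequencies must be non-negative")
  tot <- sum(object@frequencies)
  if (sum(object@counts) > 0L && abs(tot - 1) > 1e-9)
    msg <- c(msg, "frequencies of a bonded molecule must sum to 1")
  if (sum(object@counts) == 0L && tot != 0)
    msg <- c(msg, "frequencies of a bond-less molecule must be all zero")
  if (is.null(msg)) TRUE else msg
})

#' Molecule: a lightweight molecular graph read from a SMILES string
#'
#' Atoms and bonds exactly as written in the SMILES string: heavy atoms plus
#' explicitly written hydrogens, bond types resolved from the bond symbols
#' and aromaticity flags (an unmarked bond between two aromatic atoms is
#' AROMATIC, otherwise SINGLE). This string-level graph is the basis of the
#' atom and bond frequency descriptors; chemical validity checking and
#' canonical identifiers are delegated to the chemistry toolkit instead
#' (see [deriveInchikey()]).
#'
#' @slot smiles the source SMILES
#' @slot atoms data.frame with one row per atom written in the string:
#'   \code{element}, \code{aromatic}, \code{charge}, \code{hExplicit}
#'   (bracket hydrogen count), \code{hImplicit} (hydrogens implied by the
#'   organic-subset valence rules)
#' @slot bonds data.frame with \code{from}, \code{to} (1-based atom indices),
#'   \code{type} (bond-type vocabulary) and \code{order} (1, 2, 3, 4 or 1.5)
#' @slot tokenSeq the \linkS4class{TokenSequence} the graph was read from
#' @seealso [parseSmiles()], [bondProfile()], [atomFrequencies()]
#' @exportClass Molecule
setClass("Molecule",
         representation(smiles = "character",
                        atoms = "data.frame",
                        bonds = "data.frame",
                        tokenSeq = "TokenSequence"))

#' SEFConfig: which descriptor families to assemble, and how
#'
#' Configuration of a descriptor matrix: the enabled feature families, the
#' notation whose entropy is apportioned into the fractional block, the
#' padded width of that block, the hydrogen-counting mode, the folded
#' fingerprint width, and whether SMILES are canonicalized before
#' featurization.
#'
#' @slot features character vector of enabled families (see [sefConfig()])
#' @slot fracSource notation feeding the fractional block
#' @slot nMax padded width of the fractional block (NA = widest molecule in
#'   the batch)
#' @slot hydrogens \code{"explicit"} (count hydrogens only where written) or
#'   \code{"all"} (add valence-implied hydrogens)
#' @slot morganBits folded width of the optional fingerprint block
#' @slot canonicalize canonicalize SMILES before featurizing?
#' @seealso [sefConfig()], [featurizeDataset()]
#' @exportClass SEFConfig
setClass("SEFConfig",
         representation(features = "character",
                        fracSource = "character",
                        nMax = "integer",
                        hydrogens = "character",
                        morganBits = "integer",
                        canonicalize = "logical"))

.FEATURE_FAMILIES <- c("mw", "shannon_smiles", "shannon_smarts",
                       "shannon_inchikey", "shannon_bonds",
                       "frac_shannon", "bond_freq", "morgan")

setValidity("SEFConfig", function(object) {
  msg <- NULL
  if (length(object@features) == 0L)
    msg <- c(msg, "at least one feature family must be enabled")
  bad <- setdiff(object@features, .FEATURE_FAMILIES)
  if (length(bad))
    msg <- c(msg, paste("unknown feature families:", paste(bad, collapse = ", ")))
  if (!object@fracSource %in% c("SMILES", "SMARTS", "INCHIKEY"))
    msg <- c(msg, "fracSource must be SMILES, SMARTS or INCHIKEY")
  if (!object@hydrogens %in% c("explicit", "all"))
    msg <- c(msg, "hydrogens must be 'explicit' or 'all'")
  if (!is.na(object@nMax) && object@nMax < 1L)
    msg <- c(msg, "nMax must be positive")
  if (object@morganBits < 1L || object@morganBits > 4096L)
    msg <- c(msg, "morganBits must be in 1..4096")
  if (is.null(msg)) TRUE else msg
})

#' DescriptorMatrix: one descriptor row per valid molecule
#'
#' The assembled feature matrix (rows named by molecule id, columns by
#' feature name), the \linkS4class{SEFConfig} that produced it, and a table
#' of records excluded as invalid together with the reasons.
#'
#' @slot values numeric matrix, one row per valid molecule
#' @slot config the \linkS4class{SEFConfig} used
#' @slot invalid data.frame of excluded records (\code{id}, \code{smiles},
#'   \code{reason})
#' @seealso [featurizeDataset()], [writeDescriptors()], [readDescriptors()]
#' @exportClass DescriptorMatrix
setClass("DescriptorMatrix",
         representation(values = "matrix",
                        config = "SEFConfig",
                        invalid = "data.frame"))

setValidity("DescriptorMatrix", function(object) {
  msg <- NULL
  if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
  if (is.null(colnames(object@values)))
    msg <- c(msg, "values must have feature names as colnames")
  if (is.null(msg)) TRUE else msg
})
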