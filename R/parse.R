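#' @include tokenize.R
NULL

.ORGANIC_ALIPHATIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.ORGANIC_AROMATIC  <- c("b", "c", "n", "o", "p", "s")
.BOND_SYMBOLS <- c("-" = "SINGLE", "=" = "DOUBLE", "#" = "TRIPLE",
                   "$" = "QUADRUPLE", ":" = "AROMATIC",
                   "/" = "SINGLE", "\\" = "SINGLE")
.BOND_ORDER <- c(SINGLE = 1, DOUBLE = 2, TRIPLE = 3, QUADRUPLE = 4,
                 AROMATIC = 1.5, HYDROGEN = 0, IONIC = 0)

## standard valences used to infer implicit hydrogens on organic-subset atoms
.VALENCES <- list(B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5),
                  S = c(2, 4, 6), F = 1, Cl = 1, Br = 1, I = 1)

.elementEnv <- new.env(parent = emptyenv())

.elementTable <- function() {
  if (is.null(.elementEnv$tab)) {
    e <- new.env()
    utils::data("atomprop", package = "ChemmineR", envir = e)
    tab <- e$atomprop
    .elementEnv$tab <- data.frame(symbol = as.character(tab$Symbol),
                                  number = tab$Number,
                                  mass = tab$Atomic_weight,
                                  stringsAsFactors = FALSE)
  }
  .elementEnv$tab
}

.atomicNumber <- function(symbol) {
  tab <- .elementTable()
  z <- tab$number[match(symbol, tab$symbol)]
  if (anyNA(z))
    stop("unknown element symbol: ",
         paste(symbol[is.na(z)], collapse = ", "), call. = FALSE)
  z
}

.atomicMass <- function(symbol) {
  tab <- .elementTable()
  m <- tab$mass[match(symbol, tab$symbol)]
  if (anyNA(m))
    stop("unknown element symbol: ",
         paste(symbol[is.na(m)], collapse = ", "), call. = FALSE)
  m
}

.capitalize <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substring(x, 2L))
}

## Parse the inside of one bracket-atom token, e.g. "[13C@@H2+]".
.parseBracketAtom <- function(token, smiles) {
  body <- substr(token, 2L, nchar(token) - 1L)
  m <- regexec(paste0("^([0-9]+)?",                       # isotope
                      "([A-Z][a-z]?|as|se|te|si|[bcnops]|\\*)", # element
                      "(@{1,2}[A-Z]{0,2}[0-9]*)?",        # chirality
                      "(H[0-9]*)?",                       # hydrogen count
                      "(\\+{1,}[0-9]*|-{1,}[0-9]*)?",     # charge
                      "(:[0-9]+)?$"),                     # atom map
               body)[[1]]
  if (m[1L] == -1L)
    stop("cannot parse SMILES '", smiles, "': bad bracket atom '", token, "'",
         call. = FALSE)
  parts <- regmatches(body, list(m))[[1]]
  elemRaw <- parts[3L]
  aromatic <- elemRaw %in% c(.ORGANIC_AROMATIC, "as", "se", "te", "si") &&
    elemRaw == tolower(elemRaw) && elemRaw != "*"
  element <- if (elemRaw == "*") "*" else .capitalize(elemRaw)
  hPart <- parts[5L]
  hExplicit <- if (!nzchar(hPart)) 0L
               else if (hPart == "H") 1L
               else as.integer(substring(hPart, 2L))
  cPart <- parts[6L]
  charge <- if (!nzchar(cPart)) 0L else {
    sign <- if (substr(cPart, 1L, 1L) == "+") 1L else -1L
    digits <- gsub("[+-]", "", cPart)
    if (nzchar(digits)) sign * as.integer(digits)
    else sign * nchar(gsub("[0-9]", "", cPart))
  }
  list(element = element, aromatic = aromatic,
       charge = charge, hExplicit = hExplicit)
}

#' Read a SMILES string into a lightweight molecular graph
#'
#' Builds a \linkS4class{Molecule} directly from the SMILES tokens: one atom
#' per written atom (heavy atoms, plus hydrogens only where written
#' explicitly as \code{[H]} or a bracket H count), and one bond per
#' connection, typed from the string. Bond symbols map to SINGLE (\code{-},
#' \code{/}, \code{\\}), DOUBLE (\code{=}), TRIPLE (\code{#}), QUADRUPLE
#' (\code{$}) and AROMATIC (\code{:}); an unmarked bond is AROMATIC when
#' both atoms are aromatic (lowercase), SINGLE otherwise. Ring closures and
#' branches follow the usual SMILES rules. Implicit hydrogen counts are
#' inferred for organic-subset atoms from the standard valences and stored
#' in \code{atoms$hImplicit} (they are only counted as atoms under
#' \code{hydrogens = "all"}, see [atomSpecies()]).
#'
#' Validation here is syntactic (balanced brackets, branches and ring
#' closures); use [isValidSmiles()] for a chemical-toolkit parse check.
#'
#' @param smiles a single SMILES string
#' @return A \linkS4class{Molecule}.
#' @export
#' @examples
#' mol <- parseSmiles("c1ccccc1C(=O)O")
#' mol
parseSmiles <- function(smiles) {
  seq <- tokenizeSmiles(smiles)
  toks <- tokens(seq)

  atoms <- list()
  bonds <- list()
  prev <- NA_integer_
  pendingSym <- NULL
  stack <- integer(0)
  ringOpen <- list()
  insertions <- list()   # implicit-bond positions for the SMARTS writer

  addAtom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    length(atoms)
  }
  addBond <- function(from, to, type) {
    bonds[[length(bonds) + 1L]] <<- list(from = from, to = to, type = type)
  }
  bail <- function(...) {
    stop("cannot parse SMILES '", smiles, "': ", ..., call. = FALSE)
  }

  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t == "(") {
      if (!is.null(pendingSym)) bail("bond symbol before '('")
      if (is.na(prev)) bail("branch start with no preceding atom")
      stack <- c(stack, prev)
    } else if (t == ")") {
      if (!is.null(pendingSym)) bail("bond symbol before ')'")
      if (length(stack) == 0L) bail("unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (t == ".") {
      if (!is.null(pendingSym)) bail("bond symbol before '.'")
      prev <- NA_integer_
    } else if (t %in% names(.BOND_SYMBOLS)) {
      if (!is.null(pendingSym)) bail("two consecutive bond symbols")
      if (is.na(prev)) bail("bond symbol with no preceding atom")
      pendingSym <- t
    } else if (t == "~") {
      bail("unknown bond type '~' (SMARTS-only)")
    } else if (grepl("^[0-9]$|^%[0-9]{2}$", t)) {
      if (is.na(prev)) bail("ring closure with no preceding atom")
      label <- sub("^%", "", t)
      if (is.null(ringOpen[[label]])) {
        ringOpen[[label]] <- list(atom = prev, sym = pendingSym)
      } else {
        open <- ringOpen[[label]]
        ringOpen[[label]] <- NULL
        sym <- pendingSym
        if (!is.null(sym) && !is.null(open$sym) &&
            .BOND_SYMBOLS[[sym]] != .BOND_SYMBOLS[[open$sym]])
          bail("conflicting ring-bond symbols for closure ", label)
        if (is.null(sym)) sym <- open$sym
        if (is.null(sym)) {
          arom <- atoms[[open$atom]]$aromatic && atoms[[prev]]$aromatic
          type <- if (arom) "AROMATIC" else "SINGLE"
          insertions[[length(insertions) + 1L]] <-
            list(pos = i, sym = if (arom) ":" else "-")
        } else {
          type <- .BOND_SYMBOLS[[sym]]
        }
        addBond(open$atom, prev, type)
      }
      pendingSym <- NULL
    } else {
      # an atom token
      if (startsWith(t, "[")) {
        a <- .parseBracketAtom(t, smiles)
        a$bracket <- TRUE
      } else if (t %in% .ORGANIC_ALIPHATIC) {
        a <- list(element = t, aromatic = FALSE, charge = 0L,
                  hExplicit = 0L, bracket = FALSE)
      } else if (t %in% .ORGANIC_AROMATIC) {
        a <- list(element = toupper(t), aromatic = TRUE, charge = 0L,
                  hExplicit = 0L, bracket = FALSE)
      } else {
        bail("unexpected token '", t, "' at position ", i)
      }
      idx <- addAtom(a)
      if (!is.na(prev)) {
        if (is.null(pendingSym)) {
          arom <- atoms[[prev]]$aromatic && a$aromatic
          type <- if (arom) "AROMATIC" else "SINGLE"
          insertions[[length(insertions) + 1L]] <-
            list(pos = i, sym = if (arom) ":" else "-")
        } else {
          type <- .BOND_SYMBOLS[[pendingSym]]
        }
        addBond(prev, idx, type)
      }
      pendingSym <- NULL
      prev <- idx
    }
  }
  if (length(ringOpen))
    bail("unclosed ring bond(s): ", paste(names(ringOpen), collapse = ", "))
  if (length(stack)) bail("unclosed branch")
  if (!is.null(pendingSym)) bail("trailing bond symbol")
  if (length(atoms) == 0L) bail("no atoms")

  atomDf <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, NA, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    hExplicit = vapply(atoms, function(a) as.integer(a$hExplicit), 0L),
    bracket = vapply(atoms, `[[`, NA, "bracket"),
    stringsAsFactors = FALSE)
  bondDf <- if (length(bonds)) data.frame(
    from = vapply(bonds, function(b) as.integer(b$from), 0L),
    to = vapply(bonds, function(b) as.integer(b$to), 0L),
    type = vapply(bonds, `[[`, "", "type"),
    stringsAsFactors = FALSE)
  else data.frame(from = integer(0), to = integer(0),
                  type = character(0), stringsAsFactors = FALSE)
  bondDf$order <- unname(.BOND_ORDER[bondDf$type])

  atomDf$hImplicit <- .implicitHydrogens(atomDf, bondDf)

  mol <- new("Molecule", smiles = smiles, atoms = atomDf, bonds = bondDf,
             tokenSeq = seq)
  attr(mol@atoms, "smartsInsertions") <- insertions
  mol
}

## Implicit H for organic-subset (non-bracket) atoms: the smallest standard
## valence that accommodates the bond-order sum, aromatic bonds counting 1.5
## (rounded up). Bracket atoms carry exactly their written H.
.implicitHydrogens <- function(atoms, bonds) {
  n <- nrow(atoms)
  bos <- numeric(n)
  if (nrow(bonds)) {
    for (j in seq_len(nrow(bonds))) {
      bos[bonds$from[j]] <- bos[bonds$from[j]] + bonds$order[j]
      bos[bonds$to[j]] <- bos[bonds$to[j]] + bonds$order[j]
    }
  }
  bos <- ceiling(bos)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (atoms$bracket[i]) next
    val <- .VALENCES[[atoms$element[i]]]
    if (is.null(val)) next
    fit <- val[val >= bos[i]]
    if (length(fit)) out[i] <- as.integer(fit[1L] - bos[i])
  }
  out
}

#' Atom species of a molecule, in occurrence order
#'
#' The element symbols of the counted atoms, atom by atom in the order they
#' are written in the SMILES string. Under \code{hydrogens = "explicit"}
#' (the default) hydrogens enter only where the string writes them
#' (\code{[H]} atoms and bracket H counts, placed right after their heavy
#' atom); under \code{hydrogens = "all"}, valence-implied hydrogens are
#' appended after their heavy atom as well. Aromatic atoms count under
#' their element symbol (\code{c} is C).
#'
#' @param x a \linkS4class{Molecule} or a SMILES string
#' @param hydrogens \code{"explicit"} or \code{"all"}
#' @param ... unused
#' @return Character vector of element symbols, one per counted atom.
#' @export
#' @examples
#' atomSpecies("CCO")              # "C" "C" "O"
#' atomSpecies("CCO", hydrogens = "all")
setMethod("atomSpecies", "Molecule", function(x, hydrogens = c("explicit", "all"), ...) {
  hydrogens <- match.arg(hydrogens)
  atoms <- x@atoms
  out <- vector("list", nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    nH <- atoms$hExplicit[i] +
      if (hydrogens == "all") atoms$hImplicit[i] else 0L
    out[[i]] <- c(atoms$element[i], rep("H", nH))
  }
  unlist(out)
})

#' @rdname atomSpecies-Molecule-method
#' @export
setMethod("atomSpecies", "character", function(x, hydrogens = c("explicit", "all"), ...) {
  atomSpecies(parseSmiles(x), hydrogens = match.arg(hydrogens))
})

#' Atom frequency table of a molecule
#'
#' Counts the molecule's atoms by element symbol, as counted by
#' [atomSpecies()] (string-level atoms; hydrogens per the chosen mode).
#'
#' @param x a \linkS4class{Molecule} or a SMILES string
#' @param hydrogens \code{"explicit"} (default) or \code{"all"}
#' @return A \linkS4class{FrequencyTable} keyed by element symbol.
#' @export
#' @examples
#' atomFrequencies("c1ccccc1")  # C: 6
atomFrequencies <- function(x, hydrogens = c("explicit", "all")) {
  tokenFrequencies(atomSpecies(x, hydrogens = match.arg(hydrogens)))
}

#' Transliterate a SMILES string into a SMARTS pattern
#'
#' Writes the molecule as a SMARTS pattern in the style of the usual
#' toolkit SMARTS writers: every atom becomes its atomic-number primitive
#' (\code{C} and \code{c} both become \code{[#6]}, with bracket hydrogen
#' counts and charges carried along), implicit bonds are made explicit
#' (\code{-} between aliphatic atoms, \code{:} between aromatic atoms, the
#' ring-closing digit included), and explicit bond, branch, ring and stereo
#' tokens pass through unchanged.
#'
#' @param x a \linkS4class{Molecule} or a SMILES string
#' @return A single SMARTS string.
#' @export
#' @examples
#' smilesToSmarts("CCO")       # "[#6]-[#6]-[#8]"
#' smilesToSmarts("c1ccccc1")  # "[#6]1:[#6]:[#6]:[#6]:[#6]:[#6]:1"
smilesToSmarts <- function(x) {
  mol <- if (is(x, "Molecule")) x else parseSmiles(x)
  toks <- tokens(mol@tokenSeq)
  insertions <- attr(mol@atoms, "smartsInsertions")
  pre <- character(length(toks))
  for (ins in insertions) pre[ins$pos] <- ins$sym

  atomRe <- paste0("^(\\[)|^(",
                   paste(c(.ORGANIC_ALIPHATIC,
                           .ORGANIC_AROMATIC), collapse = "|"), ")$")
  ai <- 0L
  out <- character(length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    isAtom <- startsWith(t, "[") ||
      t %in% .ORGANIC_ALIPHATIC || t %in% .ORGANIC_AROMATIC
    if (isAtom) {
      ai <- ai + 1L
      a <- mol@atoms[ai, ]
      if (a$element == "*") {
        out[i] <- "[*]"
      } else {
        prim <- paste0("#", .atomicNumber(a$element))
        if (a$hExplicit > 0L)
          prim <- paste0(prim, "H",
                         if (a$hExplicit > 1L) a$hExplicit else "")
        if (a$charge != 0L)
          prim <- paste0(prim, if (a$charge > 0L) "+" else "-",
                         if (abs(a$charge) > 1L) abs(a$charge) else "")
        out[i] <- paste0("[", prim, "]")
      }
    } else {
      out[i] <- t
    }
  }
  paste0(pre, out, collapse = "")
}

#' Chemical-toolkit validity check for SMILES strings
#'
#' Asks the chemistry toolkit (OpenBabel) to parse each SMILES; a string
#' that the toolkit rejects is reported invalid. This complements the
#' syntactic checks of [parseSmiles()] with valence/aromaticity perception.
#'
#' @param smiles character vector of SMILES strings
#' @return Logical vector, TRUE where the toolkit parsed the string.
#' @export
#' @examples
#' isValidSmiles(c("CCO", "not_a_smiles"))
isValidSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
}

setMethod("show", "Molecule", function(object) {
  cat("Molecule:", object@smiles, "\n")
  cat(" ", nrow(object@atoms), "written atoms;",
      nrow(object@bonds), "bonds\n")
  if (nrow(object@bonds)) {
    tb <- table(object@bonds$type)
    cat("  bond types:",
        paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  }
})
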