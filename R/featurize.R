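#' @include entropy.R
NULL

#' Read a molecule table from CSV, SMI or SDF
#'
#' Reads molecules into the standard record table used throughout the
#' package: columns \code{id}, \code{smiles}, \code{inchikey} (NA where not
#' supplied), \code{target} (NA where not supplied), \code{valid} and
#' \code{reason}. Records whose SMILES the chemistry toolkit rejects are
#' retained with \code{valid = FALSE} and a reason, never silently dropped.
#' A one-line summary (n read / n valid) is emitted via \code{message()}.
#'
#' Formats: \code{csv} (column names configurable), \code{smi}
#' (whitespace-separated \code{SMILES [id]}, ids defaulting to line
#' numbers), \code{sdf} (structures converted to SMILES by the toolkit;
#' \code{targetCol} names a datablock field).
#'
#' @param path input file
#' @param format \code{"csv"}, \code{"smi"} or \code{"sdf"} (default: from
#'   the file extension)
#' @param smilesCol,idCol,inchikeyCol,targetCol column (or SDF field) names;
#'   only \code{smilesCol} is required for CSV
#' @return A data.frame of molecule records.
#' @export
readMolecules <- function(path, format = c("auto", "csv", "smi", "sdf"),
                          smilesCol = "smiles", idCol = NULL,
                          inchikeyCol = NULL, targetCol = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", smi = "smi", sdf = "sdf",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format=", call. = FALSE))
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
    if (!smilesCol %in% names(df))
      stop("missing SMILES column '", smilesCol, "' in ", path, call. = FALSE)
    smiles <- as.character(df[[smilesCol]])
    id <- if (!is.null(idCol) && idCol %in% names(df))
      as.character(df[[idCol]]) else sprintf("mol%04d", seq_len(nrow(df)))
    inchikey <- if (!is.null(inchikeyCol) && inchikeyCol %in% names(df))
      as.character(df[[inchikeyCol]]) else NA_character_
    target <- if (!is.null(targetCol)) {
      if (!targetCol %in% names(df))
        stop("missing target column '", targetCol, "' in ", path,
             call. = FALSE)
      as.numeric(df[[targetCol]])
    } else NA_real_
  } else if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    id <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][2L] else as.character(i)
    }, "")
    inchikey <- NA_character_
    target <- NA_real_
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    if (length(sdf) == 0L) stop("empty file: ", path, call. = FALSE)
    smiles <- as.character(ChemmineR::sdf2smiles(sdf))
    smiles <- vapply(strsplit(smiles, "[[:space:]]+"), `[[`, "", 1L)
    ids <- ChemmineR::sdfid(sdf)
    id <- ifelse(nzchar(ids), ids, sprintf("mol%04d", seq_along(smiles)))
    inchikey <- NA_character_
    target <- if (!is.null(targetCol)) {
      vapply(ChemmineR::datablock(sdf), function(db) {
        v <- suppressWarnings(as.numeric(db[targetCol]))
        if (length(v)) v else NA_real_
      }, numeric(1))
    } else NA_real_
  }
  valid <- isValidSmiles(smiles)
  reason <- ifelse(valid, "", "toolkit could not parse SMILES")
  out <- data.frame(id = id, smiles = smiles, inchikey = inchikey,
                    target = target, valid = valid, reason = reason,
                    stringsAsFactors = FALSE)
  message("readMolecules: ", nrow(out), " record(s) read, ",
          sum(out$valid), " valid")
  out
}

#' Derive canonical identifiers from a SMILES string
#'
#' \code{deriveInchikey()} returns the standard 27-character InChIKey
#' (14-10-1 layout) of each structure; \code{canonicalizeSmiles()} returns
#' the toolkit's canonical SMILES. Both are computed by OpenBabel from the
#' parsed structure, so equivalent SMILES map to one identifier and
#' stereoisomers map to different ones.
#'
#' @param smiles character vector of SMILES strings
#' @return Character vector; NA where the structure cannot be parsed.
#' @export
#' @examples
#' deriveInchikey("CCO")
deriveInchikey <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "INCHIKEY", s),
                    error = function(e) "")
    out <- trimws(out)
    if (nzchar(out)) out else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname deriveInchikey
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                    error = function(e) "")
    out <- strsplit(trimws(out), "[[:space:]]+")[[1]]
    if (length(out)) out[1L] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Molecular weight from the parsed structure
#'
#' Average-atomic-mass molecular weight (implicit hydrogens included),
#' computed by the chemistry toolkit from the parsed structure.
#'
#' @param smiles character vector of SMILES strings
#' @return Numeric vector of molecular weights, g/mol; NA on parse failure.
#' @export
#' @examples
#' molecularWeight("CCO")  # 46.07
molecularWeight <- function(smiles) {
  vapply(smiles, function(s) {
    tryCatch({
      ob <- ChemmineOB::forEachMol("SMILES", s, identity)
      ChemmineOB::prop_OB(ob)$MW
    }, error = function(e) NA_real_)
  }, numeric(1), USE.NAMES = FALSE)
}

#' ECFP4 (Morgan) fingerprints, optionally folded
#'
#' Extended-connectivity fingerprints of diameter 4 (radius 2) from the
#' chemistry toolkit, returned as a 0/1 matrix with one row per molecule.
#' The toolkit's native 4096-bit vectors are folded by bitwise OR down to
#' \code{bits} columns when a smaller width is requested.
#'
#' @param smiles character vector of SMILES strings
#' @param bits folded width (default 2048; at most 4096)
#' @return Integer 0/1 matrix, \code{length(smiles)} x \code{bits}.
#' @export
morganFingerprint <- function(smiles, bits = 2048L) {
  bits <- as.integer(bits)
  stopifnot(bits >= 1L, bits <= 4096L)
  obs <- ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"),
                                identity)
  fp <- ChemmineOB::fingerprint_OB(obs, "ECFP4")
  if (!is.matrix(fp)) fp <- matrix(fp, nrow = 1L)
  if (bits < ncol(fp)) {
    folded <- matrix(0L, nrow(fp), bits)
    idx <- ((seq_len(ncol(fp)) - 1L) %% bits) + 1L
    for (j in seq_len(ncol(fp)))
      folded[, idx[j]] <- folded[, idx[j]] | fp[, j]
    fp <- folded
  }
  storage.mode(fp) <- "integer"
  rownames(fp) <- NULL
  fp
}

#' Configure a descriptor set
#'
#' Chooses which feature families a descriptor matrix contains and how they
#' are computed. Families, emitted in this fixed column order:
#' \describe{
#'   \item{scalars}{\code{mw} (molecular weight), \code{shannon_smiles},
#'     \code{shannon_smarts}, \code{shannon_inchikey}, \code{shannon_bonds}
#'     (bond entropy, bits)}
#'   \item{\code{frac_shannon}}{the zero-padded per-atom fractional entropy
#'     block, width \code{nMax}, source \code{fracSource}}
#'   \item{\code{bond_freq}}{the 7 bond-type frequencies in vocabulary
#'     order}
#'   \item{\code{morgan}}{folded ECFP4 bits, width \code{morganBits}}
#' }
#'
#' @param features character vector of enabled families
#' @param fracSource notation whose entropy feeds the fractional block:
#'   \code{"SMILES"} (default), \code{"SMARTS"} or \code{"INCHIKEY"}
#' @param nMax padded width of the fractional block; NA (default) uses the
#'   widest molecule of the batch being featurized
#' @param hydrogens hydrogen-counting mode, see [atomSpecies()]
#' @param morganBits folded fingerprint width
#' @param canonicalize canonicalize SMILES before featurizing (off by
#'   default: the string is featurized as given)
#' @return An \linkS4class{SEFConfig}.
#' @export
#' @examples
#' sefConfig(c("shannon_smiles", "frac_shannon"), nMax = 25)
sefConfig <- function(features = c("mw", "shannon_smiles", "shannon_smarts",
                                   "shannon_inchikey", "shannon_bonds",
                                   "frac_shannon", "bond_freq"),
                      fracSource = "SMILES", nMax = NA, hydrogens = "explicit",
                      morganBits = 2048L, canonicalize = FALSE) {
  new("SEFConfig", features = features, fracSource = fracSource,
      nMax = as.integer(nMax), hydrogens = hydrogens,
      morganBits = as.integer(morganBits), canonicalize = canonicalize)
}

setMethod("show", "SEFConfig", function(object) {
  cat("SEFConfig:", paste(object@features, collapse = " + "), "\n")
  cat("  fracSource =", object@fracSource,
      "| nMax =", object@nMax, "| hydrogens =", object@hydrogens, "\n")
})

.configAsList <- function(config) {
  list(features = config@features, fracSource = config@fracSource,
       nMax = config@nMax, hydrogens = config@hydrogens,
       morganBits = config@morganBits, canonicalize = config@canonicalize)
}

#' Assemble a descriptor matrix for a set of molecules
#'
#' Computes the configured SEF descriptor columns for every valid record
#' and assembles them in the fixed column order documented in
#' [sefConfig()]. Invalid records (toolkit parse failures) are excluded
#' from the rows but listed, with reasons, in the result's \code{invalid}
#' table. Identical input and configuration yield an identical matrix.
#'
#' @param records a data.frame as returned by [readMolecules()] or
#'   [generateFixtures()], or simply a character vector of SMILES
#' @param config an \linkS4class{SEFConfig}
#' @return A \linkS4class{DescriptorMatrix}.
#' @export
#' @examples
#' dm <- featurizeDataset("CCO", sefConfig(c("shannon_smiles", "bond_freq")))
#' as.matrix(dm)
featurizeDataset <- function(records, config = sefConfig()) {
  if (is.character(records))
    records <- data.frame(id = sprintf("mol%04d", seq_along(records)),
                          smiles = records, stringsAsFactors = FALSE)
  stopifnot(is(config, "SEFConfig"))
  validObject(config)
  if (!"valid" %in% names(records)) records$valid <- isValidSmiles(records$smiles)
  if (!"reason" %in% names(records))
    records$reason <- ifelse(records$valid, "", "toolkit could not parse SMILES")
  if (!"id" %in% names(records))
    records$id <- sprintf("mol%04d", seq_len(nrow(records)))

  ok <- records[records$valid, , drop = FALSE]
  bad <- records[!records$valid, c("id", "smiles", "reason"), drop = FALSE]
  if (nrow(ok) == 0L)
    stop("empty matrix: no valid records to featurize", call. = FALSE)

  smiles <- ok$smiles
  if (config@canonicalize) smiles <- canonicalizeSmiles(smiles)
  mols <- lapply(smiles, parseSmiles)

  needKey <- any(c("shannon_inchikey") %in% config@features) ||
    config@fracSource == "INCHIKEY"
  keys <- NULL
  if (needKey) {
    keys <- if ("inchikey" %in% names(ok) && !anyNA(ok$inchikey))
      ok$inchikey else deriveInchikey(smiles)
  }

  blocks <- list()
  f <- config@features
  if ("mw" %in% f)
    blocks$mw <- matrix(molecularWeight(smiles), ncol = 1,
                        dimnames = list(NULL, "mw"))
  if ("shannon_smiles" %in% f)
    blocks$shannon_smiles <- matrix(smilesEntropy(smiles), ncol = 1,
                                    dimnames = list(NULL, "shannon_smiles"))
  if ("shannon_smarts" %in% f) {
    v <- vapply(mols, function(m)
      as.numeric(shannonEntropy(tokenizeSmarts(smilesToSmarts(m)))),
      numeric(1))
    blocks$shannon_smarts <- matrix(v, ncol = 1,
                                    dimnames = list(NULL, "shannon_smarts"))
  }
  bondProfiles <- NULL
  if (any(c("shannon_bonds", "bond_freq") %in% f))
    bondProfiles <- lapply(mols, bondProfile)
  if ("shannon_inchikey" %in% f)
    blocks$shannon_inchikey <- matrix(inchikeyEntropy(keys), ncol = 1,
                                      dimnames = list(NULL, "shannon_inchikey"))
  if ("shannon_bonds" %in% f) {
    v <- vapply(bondProfiles, entropyBits, numeric(1))
    blocks$shannon_bonds <- matrix(v, ncol = 1,
                                   dimnames = list(NULL, "shannon_bonds"))
  }
  if ("frac_shannon" %in% f) {
    totals <- switch(config@fracSource,
                     SMILES = smilesEntropy(smiles),
                     SMARTS = vapply(mols, function(m)
                       as.numeric(shannonEntropy(
                         tokenizeSmarts(smilesToSmarts(m)))), numeric(1)),
                     INCHIKEY = inchikeyEntropy(keys))
    profiles <- mapply(function(m, s)
      fractionalEntropy(m, totalEntropy = s, hydrogens = config@hydrogens),
      mols, totals, SIMPLIFY = FALSE)
    mAtoms <- vapply(profiles, function(p) length(p@perAtom), integer(1))
    nMax <- if (is.na(config@nMax)) max(mAtoms) else config@nMax
    padded <- t(vapply(profiles,
                       function(p) paddedValues(padProfile(p, nMax)),
                       numeric(nMax)))
    colnames(padded) <- sprintf("fse_%03d", seq_len(nMax))
    blocks$frac_shannon <- padded
  }
  if ("bond_freq" %in% f) {
    bf <- t(vapply(bondProfiles, function(p) p@frequencies, numeric(7)))
    colnames(bf) <- paste0("bond_", .BOND_TYPES)
    blocks$bond_freq <- bf
  }
  if ("morgan" %in% f) {
    fp <- morganFingerprint(smiles, bits = config@morganBits)
    colnames(fp) <- sprintf("morgan_%04d", seq_len(ncol(fp)))
    blocks$morgan <- fp
  }

  order <- c("mw", "shannon_smiles", "shannon_smarts", "shannon_inchikey",
             "shannon_bonds", "frac_shannon", "bond_freq", "morgan")
  mat <- do.call(cbind, blocks[intersect(order, names(blocks))])
  rownames(mat) <- ok$id
  new("DescriptorMatrix", values = mat, config = config, invalid = bad)
}

#' @rdname sef-accessors
setMethod("featureNames", "DescriptorMatrix",
          function(x) colnames(x@values))

#' @export
#' @describeIn featurizeDataset extract the numeric matrix
setMethod("as.matrix", "DescriptorMatrix", function(x, ...) x@values)

setMethod("dim", "DescriptorMatrix", function(x) dim(x@values))

setMethod("show", "DescriptorMatrix", function(object) {
  cat("DescriptorMatrix:", nrow(object@values), "molecules x",
      ncol(object@values), "features\n")
  cat("  families:", paste(object@config@features, collapse = " + "), "\n")
  if (nrow(object@invalid))
    cat("  ", nrow(object@invalid), "invalid record(s) excluded\n")
})

#' Per-atom node features and bond edge list for graph models
#'
#' Exports one row per counted atom with its element, average atomic mass
#' and fractional Shannon entropy (SMILES-based by default), optionally the
#' molecule's total SMILES entropy replicated per node, plus an edge list
#' with 0-based atom indices and the normalized bond order as edge weight
#' (bond order divided by the maximum order present in the molecule;
#' aromatic bonds count 1.5 before normalization).
#'
#' Edges connect written atoms only; hydrogens contributed by bracket H
#' counts appear as nodes bonded implicitly to no one (they carry mass and
#' entropy but no edge), matching the string-level atom count.
#'
#' @param smiles a SMILES string or \linkS4class{Molecule}
#' @param hydrogens hydrogen-counting mode, see [atomSpecies()]
#' @param includeTotalEntropy replicate the molecule's total SMILES entropy
#'   as an extra node column?
#' @return A list with data.frames \code{nodes} (\code{index}, 0-based,
#'   \code{element}, \code{mass}, \code{fracEntropy}, and optionally
#'   \code{totalEntropy}) and \code{edges} (\code{from}, \code{to} 0-based,
#'   \code{bondType}, \code{order}, \code{weight}).
#' @export
#' @examples
#' atomNodeFeatures("C=CC")$edges   # weights 1.0 and 0.5
atomNodeFeatures <- function(smiles, hydrogens = c("explicit", "all"),
                             includeTotalEntropy = TRUE) {
  hydrogens <- match.arg(hydrogens)
  mol <- if (is(smiles, "Molecule")) smiles else parseSmiles(smiles)
  sm <- smilesEntropy(mol@smiles)
  prof <- fractionalEntropy(mol, totalEntropy = sm, hydrogens = hydrogens)
  species <- prof@atomSpecies
  nodes <- data.frame(index = seq_along(species) - 1L,
                      element = species,
                      mass = .atomicMass(species),
                      fracEntropy = prof@perAtom,
                      stringsAsFactors = FALSE)
  if (includeTotalEntropy) nodes$totalEntropy <- sm

  # map written-atom indices to node rows (counted hydrogens shift them)
  nH <- mol@atoms$hExplicit +
    if (hydrogens == "all") mol@atoms$hImplicit else 0L
  nodeIdx <- cumsum(c(1L, 1L + nH[-length(nH)]))  # row of each written atom
  bonds <- mol@bonds
  if (nrow(bonds)) {
    maxOrder <- max(bonds$order)
    edges <- data.frame(from = nodeIdx[bonds$from] - 1L,
                        to = nodeIdx[bonds$to] - 1L,
                        bondType = bonds$type,
                        order = bonds$order,
                        weight = bonds$order / maxOrder,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = integer(0), to = integer(0),
                        bondType = character(0), order = numeric(0),
                        weight = numeric(0), stringsAsFactors = FALSE)
  }
  list(nodes = nodes, edges = edges)
}

#' Write / read a descriptor matrix as CSV
#'
#' \code{writeDescriptors()} writes the matrix with the molecule id as the
#' first column and the feature names as header; \code{readDescriptors()}
#' reads such a file back into a plain matrix with row and column names.
#' The pair round-trips losslessly (numbers are written at full precision).
#'
#' @param dm a \linkS4class{DescriptorMatrix} (or a plain matrix with
#'   rownames)
#' @param path output / input CSV path
#' @return \code{writeDescriptors()} the path, invisibly;
#'   \code{readDescriptors()} a numeric matrix.
#' @export
writeDescriptors <- function(dm, path) {
  mat <- if (is(dm, "DescriptorMatrix")) dm@values else dm
  if (nrow(mat) == 0L) stop("empty matrix", call. = FALSE)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDescriptors
#' @export
readDescriptors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- df[[1L]]
  mat
}
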