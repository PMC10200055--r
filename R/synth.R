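#' @include baselines.R
NULL

## The default fragment pool. Each fragment is "junction-safe": it starts
## and ends on an atom that keeps a free valence when chained by a single
## bond, so any concatenation of fragments is a chemically valid SMILES by
## construction. Token lists, atom lists and bond-type counts are recorded
## by hand, independently of the tokenizer and parser, so they can serve
## as ground truth in tests.
.FRAGMENTS <- list(
  list(smiles = "C", tokens = c("C"), atoms = c("C"), bonds = c()),
  list(smiles = "CC", tokens = c("C", "C"), atoms = c("C", "C"),
       bonds = c(SINGLE = 1)),
  list(smiles = "CCC", tokens = c("C", "C", "C"), atoms = c("C", "C", "C"),
       bonds = c(SINGLE = 2)),
  list(smiles = "CO", tokens = c("C", "O"), atoms = c("C", "O"),
       bonds = c(SINGLE = 1)),
  list(smiles = "CN", tokens = c("C", "N"), atoms = c("C", "N"),
       bonds = c(SINGLE = 1)),
  list(smiles = "CS", tokens = c("C", "S"), atoms = c("C", "S"),
       bonds = c(SINGLE = 1)),
  list(smiles = "C(F)", tokens = c("C", "(", "F", ")"), atoms = c("C", "F"),
       bonds = c(SINGLE = 1)),
  list(smiles = "C(Cl)", tokens = c("C", "(", "Cl", ")"),
       atoms = c("C", "Cl"), bonds = c(SINGLE = 1)),
  list(smiles = "C(Br)", tokens = c("C", "(", "Br", ")"),
       atoms = c("C", "Br"), bonds = c(SINGLE = 1)),
  list(smiles = "C=C", tokens = c("C", "=", "C"), atoms = c("C", "C"),
       bonds = c(DOUBLE = 1)),
  list(smiles = "C#C", tokens = c("C", "#", "C"), atoms = c("C", "C"),
       bonds = c(TRIPLE = 1)),
  list(smiles = "C(=O)", tokens = c("C", "(", "=", "O", ")"),
       atoms = c("C", "O"), bonds = c(DOUBLE = 1)),
  list(smiles = "c1ccccc1",
       tokens = c("c", "1", "c", "c", "c", "c", "c", "1"),
       atoms = rep("C", 6), bonds = c(AROMATIC = 6)),
  list(smiles = "C1CCCCC1",
       tokens = c("C", "1", "C", "C", "C", "C", "C", "1"),
       atoms = rep("C", 6), bonds = c(SINGLE = 6)))

#' The default synthetic fragment pool
#'
#' Fourteen small drug-like SMILES fragments (alkyl chains, ether, amine
#' and thioether links, halogen and carbonyl substituents, alkene, alkyne,
#' benzene and cyclohexane), each carrying hand-recorded token, atom and
#' bond-type ground truth. Fragments are designed so that concatenating any
#' of them in any order yields a parseable, chemically valid SMILES.
#'
#' @return A list of fragment entries (\code{smiles}, \code{tokens},
#'   \code{atoms}, \code{bonds}).
#' @export
sefFragmentPool <- function() .FRAGMENTS

#' Generate synthetic molecule fixtures with known compositions
#'
#' Assembles molecules by concatenating 1 to \code{maxFragments} fragments
#' from the pool (fragment junctions add one SINGLE bond each), which
#' keeps every emitted SMILES chemically valid by construction, and
#' attaches a target generated by the chosen rule:
#' \describe{
#'   \item{linear_in_entropy}{\eqn{y = a S_m + b + \epsilon} with the
#'     molecule's SMILES entropy \eqn{S_m} and
#'     \eqn{\epsilon \sim N(0, \sigma^2)}}
#'   \item{linear_in_mw}{\eqn{y = a \cdot MW + b + \epsilon}}
#'   \item{binary_threshold}{label 1 where the linear-in-entropy latent
#'     value exceeds its median}
#' }
#' Each record carries its exact token multiset, atom counts and bond-type
#' counts, assembled from the hand-recorded fragment truth tables, for use
#' as an independent ground truth in tests. The output is deterministic
#' under \code{seed}; in the unexpected event that an assembled string
#' fails the toolkit parse it is rejected and resampled, and the resample
#' count is reported.
#'
#' @param nMolecules number of fixtures
#' @param pool fragment pool, see [sefFragmentPool()]
#' @param targetRule \code{"linear_in_entropy"} (default),
#'   \code{"linear_in_mw"} or \code{"binary_threshold"}
#' @param coefA,coefB coefficients of the target rule (defaults a = 2,
#'   b = 0)
#' @param sigma target noise standard deviation (default 0.1)
#' @param seed integer seed
#' @param maxFragments maximum fragments per molecule (default 4)
#' @return A list with \code{records} (data.frame \code{id}, \code{smiles},
#'   \code{target}), \code{truth} (per-molecule list of \code{tokenCounts},
#'   \code{atomCounts}, \code{bondCounts}) and \code{resampled}.
#' @export
#' @examples
#' fx <- generateFixtures(5, seed = 7)
#' fx$records
generateFixtures <- function(nMolecules, pool = sefFragmentPool(),
                             targetRule = c("linear_in_entropy",
                                            "linear_in_mw",
                                            "binary_threshold"),
                             coefA = 2, coefB = 0, sigma = 0.1,
                             seed = 1L, maxFragments = 4L) {
  targetRule <- match.arg(targetRule)
  stopifnot(nMolecules >= 1L, length(pool) >= 1L)
  set.seed(seed)

  smiles <- character(nMolecules)
  truth <- vector("list", nMolecules)
  resampled <- 0L
  for (i in seq_len(nMolecules)) {
    repeat {
      nf <- sample.int(maxFragments, 1L)
      frags <- pool[sample.int(length(pool), nf, replace = TRUE)]
      smi <- paste(vapply(frags, `[[`, "", "smiles"), collapse = "")
      if (isValidSmiles(smi)) break
      resampled <- resampled + 1L
    }
    toks <- unlist(lapply(frags, `[[`, "tokens"))
    atoms <- unlist(lapply(frags, `[[`, "atoms"))
    bonds <- unlist(lapply(frags, `[[`, "bonds"))
    if (nf > 1L) bonds <- c(bonds, SINGLE = nf - 1L)
    bondCounts <- if (length(bonds))
      tapply(unname(bonds), names(bonds), sum) else integer(0)
    smiles[i] <- smi
    truth[[i]] <- list(
      tokenCounts = table(toks),
      atomCounts = table(atoms),
      bondCounts = if (length(bondCounts))
        stats::setNames(as.integer(bondCounts), names(bondCounts))
      else integer(0))
  }

  latentBase <- switch(targetRule,
                       linear_in_mw = molecularWeight(smiles),
                       smilesEntropy(smiles))
  noise <- if (sigma > 0) stats::rnorm(nMolecules, 0, sigma) else 0
  latent <- coefA * latentBase + coefB + noise
  target <- if (targetRule == "binary_threshold")
    as.numeric(latent > stats::median(latent)) else latent

  records <- data.frame(id = sprintf("syn%04d", seq_len(nMolecules)),
                        smiles = smiles, target = target,
                        stringsAsFactors = FALSE)
  names(truth) <- records$id
  list(records = records, truth = truth, resampled = resampled)
}

#' Write a fixture set as .smi plus a truth CSV
#'
#' Writes \code{fixtures.smi} (SMILES and id per line), \code{targets.csv}
#' (id, smiles, target) and \code{truth.csv} (long-format id / kind / item
#' / count rows for the token, atom and bond ground truth) into a
#' directory.
#'
#' @param fixtures output of [generateFixtures()]
#' @param dir output directory (created if needed)
#' @return The directory, invisibly.
#' @export
writeFixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rec <- fixtures$records
  writeLines(paste(rec$smiles, rec$id), file.path(dir, "fixtures.smi"))
  utils::write.csv(rec, file.path(dir, "targets.csv"), row.names = FALSE)
  rows <- do.call(rbind, lapply(rec$id, function(id) {
    tr <- fixtures$truth[[id]]
    do.call(rbind, lapply(c("tokenCounts", "atomCounts", "bondCounts"),
                          function(kind) {
      v <- tr[[kind]]
      if (length(v) == 0L) return(NULL)
      data.frame(id = id, kind = kind, item = names(v),
                 count = as.integer(v), stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(rows, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
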