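---
title: "Shannon entropy descriptors: methods and design notes"
author: "SEFtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shannon entropy descriptors: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SEFtools)
```

# The descriptor model

SEFtools treats a molecule's string representations as information sources
and uses their Shannon entropy as molecular descriptors. For a string that
splits into tokens $x_i$ with counts $n_i$ out of $N$ total, the entropy is

$$S_m = -\sum_i^k f_i \log_2 f_i, \qquad f_i = n_i / N,$$

in bits, with $k$ distinct tokens. Three notations are supported:

* **SMILES**, split atom-wise: bracket atoms (`[C@@H]`, `[nH]`) are single
  tokens, the halogen digraphs `Cl`/`Br` are single tokens, `%nn` ring
  closures are single tokens, and every other character (aromatic atoms,
  bond symbols, parentheses, ring digits) is one token. The split is
  lossless — concatenating the tokens reproduces the string — which the
  `TokenSequence` class enforces as a validity invariant.
* **SMARTS**, same grammar with the SMARTS operators falling through as
  single characters.
* **InChIKey**, split character-wise (hyphens included).

Two derived families complete the framework.

**Fractional Shannon entropy.** The molecule's total entropy is
apportioned over its atoms by atom-count fraction, the way total pressure
distributes into partial pressures in a gas mixture: species $j$ with
$f_j$ of the counted atoms carries $s_j = f_j S_m$ on each of its atoms.
Two invariants follow and are enforced: all atoms of one species share one
value, and the distinct-species values sum to $S_m$ exactly. Because
molecules differ in size, per-atom vectors are zero-padded to a common
width $N$, $(N-m)/2$ zeros on each side for a molecule of $m$ atoms.

**Bond profile.** Bonds are counted over the fixed, ordered vocabulary
`SINGLE, DOUBLE, TRIPLE, QUADRUPLE, AROMATIC, HYDROGEN, IONIC`; the
frequency vector (summing to 1 for any bonded molecule) and/or its scalar
entropy $S_{bf}$ enter the descriptor matrix. The last two types never
arise from covalent SMILES input but keep the block width stable across
datasets.

## Where the numbers come from: string-level chemistry

The descriptors are defined on the *representation*, so atoms and bonds
are read from the SMILES string itself by the package's own lightweight
graph reader rather than from a round trip through a structure file:

* Atom counting. Heavy atoms count as written; aromatic `c` counts under
  element C; hydrogens count only where the string writes them (`[H]`
  atoms, bracket H counts). This is the `hydrogens = "explicit"` default:
  implicit hydrogens never appear in the string, so they carry no tokens
  and, by the same logic, no atoms. A `hydrogens = "all"` mode adds
  valence-implied hydrogens (standard valences B 3, C 4, N 3/5, O 2,
  P 3/5, S 2/4/6, halogens 1; aromatic bonds counting 1.5, rounded up) for
  users who prefer structure-level counting; the choice is a configuration
  flag and is recorded in the matrix provenance.
* Bond typing. Explicit symbols map to their types (`-`, `/`, `\` single;
  `=` double; `#` triple; `$` quadruple; `:` aromatic); an unmarked bond
  between two aromatic atoms is AROMATIC, otherwise SINGLE. This keeps
  benzene's six ring bonds aromatic, where a kekulized structure-file
  round trip would alternate single/double and change both the bond block
  and its entropy.

Chemical validity checking, canonical SMILES, InChIKeys, molecular weight
and ECFP4 fingerprints are delegated to the OpenBabel toolkit (via
ChemmineOB): those are structure-level, standard computations. The ECFP4
implementation is OpenBabel's (diameter 4, native 4096-bit, folded by OR
to the configured width); other toolkits' ECFP4 bit assignments differ in
detail, so Tanimoto similarities are comparable within one toolkit, which
is how the kNN baseline uses them.

SMARTS patterns are produced by transliterating the parsed SMILES —
atoms become atomic-number primitives (`C` and `c` both `[#6]`, bracket H
counts and charges carried along) and implicit bonds are made explicit
(`-` aliphatic, `:` aromatic, including before ring-closing digits) — the
convention of the common toolkit SMARTS writers. Where SMARTS strings come
from is a convention, not part of the entropy definition; users can supply
their own patterns via `smartsEntropy(x, fromSmiles = FALSE)`.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `features` | scalars + fractional + bond blocks | which families enter the matrix, in the fixed order scalars, fractional block, bond block, fingerprint bits |
| `fracSource` | `"SMILES"` | notation whose entropy is apportioned; the rule is agnostic of the source, so InChIKey- or SMARTS-based fractional blocks are one flag away |
| `nMax` | widest molecule in the batch | padded width (atoms); set it explicitly when train and test matrices must align |
| `hydrogens` | `"explicit"` | string-level (default) vs structure-level atom counting, see above |
| `morganBits` | 2048 | folded ECFP4 width |
| `canonicalize` | `FALSE` | featurize the string as given (default) or its canonical form |
| kNN `kSweep` | 1, 2, 3 | candidate neighbourhood sizes; chosen on a 20% validation split of the training set, never on test |
| RF grids | 25/100/200 trees, 1/2/5 leaf, 2/3/5 split | full 3×3×3 grid, ≥5-fold CV, best refit on all of train |

Canonicalization is off by default deliberately: entropy is a property of
the string, and two equivalent SMILES of one molecule generally have
different entropies. A "unique numerical representation per molecule" only
holds over canonical strings, so the flag exists; featurizing as-given is
the default because input strings are what the user chose to describe
their data with, and silently rewriting them would make results depend on
the toolkit's canonical form.

# Numerical choices

* Logarithms are base 2 throughout; all entropies are reported in bits.
* $0 \log 0 := 0$; a table with a single distinct item returns exactly
  `0.0`, not a floating-point residue.
* Frequencies are formed as exact integer ratios `count/total` before the
  logarithm, avoiding accumulation error; the test suite holds the
  implementation to within $10^{-12}$ bits of an independently written
  brute-force evaluator over randomized token strings.
* Odd padding split: $\lfloor (N-m)/2 \rfloor$ zeros left,
  $\lceil (N-m)/2 \rceil$ right. The halved padding is exact only for even
  $N-m$; fixing the convention keeps batches reproducible.
* kNN ties at the $k$-th similarity rank resolve by stable training-set
  order; classification vote ties resolve toward the more similar
  neighbour. Molecules with all-zero fingerprints have undefined Tanimoto
  similarity and are returned as flagged `NA` predictions rather than
  silently guessed.
* MAPE excludes zero-truth rows and reports how many were excluded; $R^2$
  on a zero-variance truth vector is `NA` with an explicit flag.
* The RF grid is evaluated by `cvFolds`-fold CV (minimum 5) with fold
  assignment and tree growth both derived from the user's seed, so
  identical seeds give bit-identical predictions. The forest itself is
  ranger; its `min.node.size` is the minimum node size eligible for a
  split and `min.bucket` the minimum terminal-node size, matching the
  minimum-samples-to-split / minimum-samples-per-leaf grid semantics.

# The synthetic generator

`generateFixtures()` assembles molecules by concatenating 1–4 fragments
from a 14-fragment pool (alkyl chains, ether/amine/thioether links,
halogen and carbonyl substituents, alkene, alkyne, benzene, cyclohexane).
Every fragment starts and ends on an atom with a free valence, so any
concatenation is a chemically valid SMILES by construction; each junction
contributes one SINGLE bond. Every record carries hand-recorded token,
atom and bond ground truth assembled from the per-fragment tables — an
independent second path against which tokenizer, parser and bond profiler
are tested. Targets follow a declared rule: linear in entropy
($y = aS_m + b + \varepsilon$, defaults $a = 2$, $b = 0$,
$\sigma = 0.1$), linear in molecular weight, or a binary threshold on the
entropy latent. The default noise level keeps the signal dominant but
non-trivial at desk scale; the baseline-recovery checks use
$\sigma = 0.01$ with $n = 200$ molecules (150 train / 50 test), sizes at
which the full RF grid with 5-fold CV runs in well under a minute.

What the generator emulates: small drug-like molecules with known
compositions and a target that genuinely depends on a descriptor. What it
does not emulate: realistic chemical-space coverage, activity cliffs,
assay noise structure, or the property distributions of curated
bioactivity datasets. Passing tests therefore demonstrate that the
descriptors and models compute what they claim and recover planted
signal — not that SEF descriptors will improve any particular real-world
QSAR benchmark. One practical artefact of fragment assembly: the same
molecule can be emitted under two different SMILES (e.g. `CC(F)` and
`C(F)C`), so structure-level checks (like the kNN perfect-memory
property) deduplicate records by InChIKey first.

# Open design decisions

* Tokenizer: the atom-wise regex grammar was chosen over learned pair
  encodings because it is deterministic, lossless and needs no trained
  merge table; pair-encoding merges are a non-goal.
* Entropies are per-molecule (frequencies from the molecule's own
  tokens), not referenced to a corpus-wide vocabulary; the token sets are
  exposed (`tokens()`, `tokenFrequencies()`) so a corpus-level variant
  could be layered on top.
* The fractional block accepts any entropy source, because apportioning
  is independent of where $S_m$ came from.
* kNN model selection happens on a held-out validation split rather than
  on the test set, avoiding the leakage a naive "best k" would allow.
* Metrics for stochastic models are reported as mean ± sd over at least
  five independent runs (`summarizeReplicates()`).

# Limitations

* String-level atom counting means entropies change with the written
  form unless canonicalization is enabled — that is a property of the
  method, documented rather than hidden.
* The SMILES reader covers the organic subset, bracket atoms, branches,
  ring closures (including `%nn`), stereo marks, charges and isotopes; it
  is not a full aromaticity-perceiving chemistry engine, by design — the
  toolkit handles structure-level tasks.
* HYDROGEN and IONIC bond types are carried in the vocabulary but never
  produced from covalent SMILES input.
* ROC AUC uses the rank statistic with average ranks for ties; it is
  cross-checked against pROC in the test suite.
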