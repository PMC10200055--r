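# SEFtools

Shannon entropy framework (SEF) molecular descriptors for QSAR modelling,
with the reference baseline models used to benchmark them.

## The problem

Property-prediction models in drug discovery need numerical descriptions of
molecules. Most descriptor families encode either structure (fingerprints)
or physics (molecular weight, logP). SEF descriptors instead measure the
*information content* of a molecule's string representations. For a
molecule whose string splits into tokens with relative frequencies
`f_i = n_i / N`, the string's Shannon entropy is

    S_m = - Σ_i f_i · log2(f_i)        [bits]

computed over SMILES tokens (atom-wise tokenizer), SMARTS tokens, or the
characters of the InChIKey. Two derived feature families complete the set:

* **Fractional Shannon entropy** — `S_m` apportioned over the molecule's
  atoms by atom-count fraction, `s_j = f_j · S_m` for species j, the way
  total pressure distributes into partial pressures in a gas mixture.
  Every atom of one species carries the same value, and summing over
  distinct species recovers `S_m` exactly. Per-atom vectors are zero-padded
  `(N − m)/2` on each side to a common width `N` so a batch forms a matrix.
* **Bond-type frequencies** — occurrence frequencies over the fixed
  vocabulary `SINGLE, DOUBLE, TRIPLE, QUADRUPLE, AROMATIC, HYDROGEN,
  IONIC`, optionally reduced to a scalar bond entropy
  `S_bf = -Σ f_b log2 f_b`.

These descriptors are cheap, deterministic, stereochemistry-sensitive (a
cis/trans pair already differs in its SMILES token multiset and its
InChIKey), and weakly correlated with standard descriptors, which makes
them useful companions to MW or fingerprints in regression and
classification models.

The package also implements the two desk-scale reference models these
descriptors are usually benchmarked against — a Tanimoto-similarity kNN
over ECFP4 fingerprints (k swept over 1, 2, 3 on a validation split) and a
random forest grid-searched over trees {25, 100, 200}, minimum samples per
leaf {1, 2, 5} and minimum samples to split {2, 3, 5} with ≥5-fold
cross-validation — plus the standard metrics (MAPE, MAE, RMSE, R², ROC
AUC, accuracy).

## Worked example

```r
library(SEFtools)

smilesEntropy("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
#> [1] 2.665429

perAtom(fractionalEntropy("CCO"))        # ethanol: s_C, s_C, s_O
#> [1] 0.6121972 0.6121972 0.3060986

bondProfile("CC(=O)Oc1ccccc1C(=O)O")
#> BondProfile: CC(=O)Oc1ccccc1C(=O)O
#>    SINGLE:5 DOUBLE:2 AROMATIC:6
#>   S_bf = 1.460485 bits
```

Ethanol's SMILES has token counts {C: 2, O: 1}, so `S_m = log2(3) − 2/3 ≈
0.918` bits; carbon's fraction 2/3 gives each C atom `0.612` bits and the O
atom `0.306` bits — the three distinct-species values sum back to `S_m`.
Aspirin's 13 bonds split 5/2/6 over single/double/aromatic, giving a bond
entropy of 1.46 bits.

A full modelling round on synthetic fixtures (the generator emits
parseable molecules with known token/atom/bond compositions and a target
that is a stated function of entropy plus noise):

```r
fx <- generateFixtures(200, sigma = 0.01, coefA = 2, seed = 106)
dm <- featurizeDataset(fx$records,
        sefConfig(c("mw", "shannon_smiles", "shannon_bonds",
                    "frac_shannon", "bond_freq")))
dm
#> DescriptorMatrix: 200 molecules x 26 features
#>   families: mw + shannon_smiles + shannon_bonds + frac_shannon + bond_freq

x <- as.matrix(dm); tr <- seq_len(150)
fit <- rfFitPredict(x[tr, ], fx$records$target[tr], x[-tr, ], seed = 107)
fit$best                                  # chosen from the declared grids
#> $numTrees 200  $minLeaf 1  $minSplit 3
evaluatePredictions(fit$predictions, fx$records$target[-tr])$r2
#> [1] 0.9753458
```

The forest recovers the linear-in-entropy target on held-out molecules
(R² ≈ 0.98), as it should when the generating feature is in the matrix.

## Command line

A thin launcher over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","sef.R",package="SEFtools"))')" \
    entropy --smiles "CCO"
# 0.918296
```

Subcommands: `entropy`, `featurize`, `baseline`, `fixtures`. Every
file-writing run leaves a `*.provenance.json` (configuration + package
version) next to its output.

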