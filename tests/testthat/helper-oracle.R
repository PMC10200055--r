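# Brute-force Shannon entropy oracle: a second, independent implementation
# of -sum(f log2 f). The dictionary is built with an environment and an
# explicit loop, and the log sum is accumulated term by term, sharing no
# code with the package's vectorized exact-ratio path.
oracleEntropy <- function(tokens) {
  stopifnot(length(tokens) > 0L)
  dict <- new.env(parent = emptyenv())
  for (t in tokens) {
    old <- if (exists(t, envir = dict, inherits = FALSE))
      get(t, envir = dict) else 0L
    assign(t, old + 1L, envir = dict)
  }
  n <- length(tokens)
  s <- 0
  for (key in ls(dict, all.names = TRUE)) {
    p <- get(key, envir = dict) / n
    s <- s - p * log(p) / log(2)
  }
  s
}

# random token strings over a small alphabet, for oracle-equivalence runs
randomTokenString <- function(maxLen = 40L,
                              alphabet = c(LETTERS[1:8], "=", "#", "(", ")")) {
  sample(alphabet, sample.int(maxLen, 1L), replace = TRUE)
}

# a stress set of SMILES covering bracket atoms, %nn ring closures,
# stereo marks, charges and multi-ring systems
stressSmiles <- function() {
  c("C", "CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
    "[C@@H](Br)Cl", "F/C=C/F", "F/C=C\\F",
    "C%10CCCC%10", "c1ccc2ccccc2c1", "[NH4+].[Cl-]",
    "O=C(O)c1ccccc1", "[13CH4]", "N#Cc1ccccc1",
    "C1=CC=CC=C1", "[O-]C(=O)C", "C$C")
}
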