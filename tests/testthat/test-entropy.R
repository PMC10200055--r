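# frozen expected values, computed with exact fractions:
#   -(2/3 log2(2/3) + 1/3 log2(1/3)) = log2(3) - 2/3
ENT_2_1 <- log2(3) - 2 / 3   # 0.9182958340544896

test_that("token frequency tables count the multiset, order-independently", {
  ft <- tokenFrequencies(c("C"))
  expect_identical(counts(ft), c(C = 1L))
  expect_identical(totalCount(ft), 1L)
  expect_identical(uniqueCount(ft), 1L)

  ft <- tokenFrequencies(c("C", "C", "O"))
  expect_identical(counts(ft)[["C"]], 2L)
  expect_identical(counts(ft)[["O"]], 1L)
  expect_identical(totalCount(ft), 3L)
  expect_identical(uniqueCount(ft), 2L)

  expect_identical(counts(tokenFrequencies(c("A", "A", "B"))),
                   counts(tokenFrequencies(c("B", "A", "A"))))
  expect_error(tokenFrequencies(character(0)), "empty")
})

test_that("Shannon entropy matches closed forms exactly", {
  expect_identical(as.numeric(shannonEntropy(c("C"))), 0)
  expect_identical(as.numeric(shannonEntropy(rep("C", 9))), 0)
  expect_equal(as.numeric(shannonEntropy(c("C", "O"))), 1)
  expect_equal(as.numeric(shannonEntropy(c("C", "C", "O"))), ENT_2_1,
               tolerance = 1e-15)
  expect_equal(smilesEntropy("CCO"), ENT_2_1, tolerance = 1e-15)
  # uniform over k symbols hits the log2(k) upper bound exactly
  for (k in c(2L, 4L, 8L))
    expect_equal(as.numeric(shannonEntropy(LETTERS[seq_len(k)])), log2(k))
})

test_that("entropy agrees with the brute-force oracle and obeys its bounds", {
  set.seed(42)
  for (i in 1:300) {
    toks <- randomTokenString()
    ft <- tokenFrequencies(toks)
    s <- as.numeric(shannonEntropy(ft))
    expect_lt(abs(s - oracleEntropy(toks)), 1e-12)
    k <- uniqueCount(ft)
    expect_gte(s, 0)
    expect_lte(s, log2(k) + 1e-12)
    # permutation invariance
    expect_identical(s, as.numeric(shannonEntropy(sample(toks))))
  }
})

test_that("atom frequencies count string-level atoms by element", {
  expect_identical(counts(atomFrequencies("C")), c(C = 1L))
  ft <- atomFrequencies("CCO")
  expect_identical(counts(ft)[["C"]], 2L)
  expect_identical(counts(ft)[["O"]], 1L)
  # aromatic carbons count under element C
  expect_identical(counts(atomFrequencies("c1ccccc1")), c(C = 6L))
  # bracket hydrogens are explicit atoms; implicit ones are not
  expect_identical(counts(atomFrequencies("[NH4+]")), c(H = 4L, N = 1L))
  expect_identical(counts(atomFrequencies("CCO", hydrogens = "all")),
                   c(C = 2L, H = 6L, O = 1L))
  expect_error(atomFrequencies("C]C"), "unmatched")
})

test_that("fractional entropy apportions S_m by atom-count fraction", {
  p <- fractionalEntropy("C")
  expect_identical(perAtom(p), 0)

  p <- fractionalEntropy("CCO")
  expect_equal(perAtom(p), c(2, 2, 1) / 3 * ENT_2_1, tolerance = 1e-15)
  # distinct-species sum recovers S_m
  bySpecies <- tapply(perAtom(p), atomSpecies(p), unique)
  expect_equal(sum(bySpecies), ENT_2_1, tolerance = 1e-15)

  # the apportioning rule is agnostic of the entropy source
  key <- deriveInchikey("CCO")
  p2 <- fractionalEntropy("CCO", totalEntropy = inchikeyEntropy(key))
  expect_equal(sum(tapply(perAtom(p2), atomSpecies(p2), unique)),
               inchikeyEntropy(key), tolerance = 1e-12)
})

test_that("same-species atoms share one value across a fixture batch", {
  fx <- generateFixtures(40, seed = 11)
  for (smi in fx$records$smiles) {
    p <- fractionalEntropy(smi)
    sp <- split(perAtom(p), atomSpecies(p))
    expect_true(all(vapply(sp, function(v) length(unique(v)) == 1L,
                           logical(1))))
    expect_lt(abs(sum(vapply(sp, `[[`, 0, 1L)) - smilesEntropy(smi)), 1e-12)
  }
})

test_that("padding splits zeros floor-left / ceiling-right and conserves sums", {
  p3 <- padProfile(fractionalEntropy("CCO"), 7)
  v <- c(2, 2, 1) / 3 * ENT_2_1
  expect_equal(paddedValues(p3), c(0, 0, v, 0, 0), tolerance = 1e-15)

  p1 <- padProfile(fractionalEntropy("C"), 1)
  expect_identical(paddedValues(p1), 0)

  # odd N - m: one zero left, two right
  p2 <- padProfile(fractionalEntropy("CO"), 5)
  expect_identical(which(paddedValues(p2) != 0), 2:3)
  expect_identical(sum(paddedValues(p2)), sum(perAtom(p2)))
  expect_length(paddedValues(p2), 5L)

  expect_error(padProfile(fractionalEntropy("CCO"), 2),
               "3 atoms but nMax is 2")
})

test_that("bond profiles follow the fixed vocabulary and its entropy", {
  bp <- bondProfile("CCO")
  expect_identical(unname(bondFrequencies(bp)), c(1, 0, 0, 0, 0, 0, 0))
  expect_identical(entropyBits(bp), 0)

  bp <- bondProfile("C=CC")
  expect_identical(unname(bondFrequencies(bp)), c(0.5, 0.5, 0, 0, 0, 0, 0))
  expect_identical(entropyBits(bp), 1)

  bp <- bondProfile("c1ccccc1")
  expect_identical(unname(bondCounts(bp)),
                   c(0L, 0L, 0L, 0L, 6L, 0L, 0L))
  expect_identical(entropyBits(bp), 0)

  # quadruple bonds are in the vocabulary; bond-less molecules are all-zero
  expect_identical(unname(bondCounts(bondProfile("C$C"))),
                   c(0L, 0L, 0L, 1L, 0L, 0L, 0L))
  expect_identical(sum(bondFrequencies(bondProfile("C"))), 0)
  expect_error(bondProfile("C~C"), "unknown bond type")
})

test_that("bond entropy is zero exactly when at most one bond type occurs", {
  fx <- generateFixtures(40, seed = 12)
  for (smi in fx$records$smiles) {
    bp <- bondProfile(smi)
    nTypes <- sum(bondCounts(bp) > 0)
    if (nTypes <= 1L) expect_identical(entropyBits(bp), 0)
    else expect_gt(entropyBits(bp), 0)
    if (sum(bondCounts(bp)) > 0)
      expect_equal(sum(bondFrequencies(bp)), 1, tolerance = 1e-15)
  }
})

test_that("stereoisomer pairs separate in the (SMILES, InChIKey) entropy pair", {
  cis <- "F/C=C\\F"; trans <- "F/C=C/F"
  sPair <- smilesEntropy(c(trans, cis))
  expect_false(sPair[1] == sPair[2])
  keys <- deriveInchikey(c(trans, cis))
  expect_false(keys[1] == keys[2])
  kPair <- inchikeyEntropy(keys)
  expect_false(sPair[1] == sPair[2] && kPair[1] == kPair[2])
})
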