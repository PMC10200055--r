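test_that("fixture generation is deterministic and valid by construction", {
  one <- generateFixtures(1, pool = sefFragmentPool()[1], seed = 0,
                          maxFragments = 1)
  expect_identical(one$records$smiles, "C")
  expect_identical(as.integer(one$truth[[1]]$tokenCounts[["C"]]), 1L)

  a <- generateFixtures(100, seed = 7)
  b <- generateFixtures(100, seed = 7)
  expect_identical(a, b)
  expect_identical(a$resampled, 0L)
  expect_true(all(isValidSmiles(a$records$smiles)))
})

test_that("generator ground truth agrees with tokenizer, parser and bonds", {
  fx <- generateFixtures(50, seed = 13)
  for (i in seq_len(50)) {
    smi <- fx$records$smiles[i]
    tr <- fx$truth[[i]]

    got <- table(tokens(tokenizeSmiles(smi)))
    want <- tr$tokenCounts
    expect_identical(sort(names(got)), sort(names(want)))
    expect_identical(as.integer(got[names(want)]), as.integer(want))

    gotAtoms <- table(atomSpecies(smi))
    expect_identical(as.integer(gotAtoms[names(tr$atomCounts)]),
                     as.integer(tr$atomCounts))

    bc <- bondCounts(bondProfile(smi))
    expect_identical(sum(bc), sum(tr$bondCounts))
    for (tp in names(tr$bondCounts))
      expect_identical(as.integer(bc[[tp]]), as.integer(tr$bondCounts[[tp]]))
  }
})

test_that("targets obey their generating rule exactly at sigma = 0", {
  fx <- generateFixtures(30, sigma = 0, coefA = 2, coefB = 1, seed = 17)
  expect_equal(fx$records$target, 2 * smilesEntropy(fx$records$smiles) + 1,
               tolerance = 1e-14)

  fx <- generateFixtures(30, targetRule = "linear_in_mw", sigma = 0,
                         coefA = 0.5, seed = 17)
  expect_equal(fx$records$target, 0.5 * molecularWeight(fx$records$smiles),
               tolerance = 1e-10)

  fx <- generateFixtures(30, targetRule = "binary_threshold", seed = 17)
  expect_true(all(fx$records$target %in% c(0, 1)))
  expect_true(any(fx$records$target == 1) && any(fx$records$target == 0))
})

test_that("fixture sets write as .smi plus truth tables", {
  fx <- generateFixtures(6, seed = 19)
  dir <- file.path(tempdir(), "fixtures-out")
  writeFixtures(fx, dir)
  expect_true(file.exists(file.path(dir, "fixtures.smi")))
  suppressMessages(rec <- readMolecules(file.path(dir, "fixtures.smi")))
  expect_identical(rec$smiles, fx$records$smiles)
  truth <- read.csv(file.path(dir, "truth.csv"))
  expect_true(all(c("tokenCounts", "atomCounts", "bondCounts") %in%
                    truth$kind))
  unlink(dir, recursive = TRUE)
})

test_that("the oracle itself passes its closed-form anchors", {
  expect_identical(oracleEntropy("C"), 0)
  expect_lt(abs(oracleEntropy(c("C", "C", "O")) - (log2(3) - 2 / 3)), 1e-12)
  expect_equal(oracleEntropy(c("A", "B", "C", "D")), 2)
})
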