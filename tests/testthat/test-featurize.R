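ENT_2_1 <- log2(3) - 2 / 3

test_that("CSV and .smi molecule tables read with invalid rows retained", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("name,smiles,activity",
               "m1,CCO,0.5",
               "m2,not_a_smiles,0.7",
               "m3,c1ccccc1,1.2"), csv)
  suppressMessages(
    rec <- readMolecules(csv, smilesCol = "smiles", idCol = "name",
                         targetCol = "activity"))
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$valid, c(TRUE, FALSE, TRUE))
  expect_match(rec$reason[2], "could not parse")
  expect_identical(rec$target, c(0.5, 0.7, 1.2))

  smi <- tempfile(fileext = ".smi")
  writeLines(c("CCO mol_a", "CCC", "c1ccccc1 mol_c"), smi)
  suppressMessages(rec <- readMolecules(smi))
  expect_identical(rec$id, c("mol_a", "2", "mol_c"))
  expect_true(all(rec$valid))

  expect_error(suppressMessages(readMolecules(csv, smilesCol = "nope")),
               "missing SMILES column")
  expect_error(readMolecules("no_such_file.csv"), "not found")
})

test_that("SDF structures round in through the toolkit", {
  sdfFile <- tempfile(fileext = ".sdf")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(c(a = "CCO", b = "CCN")))
  ChemmineR::write.SDF(sdf, sdfFile)
  suppressMessages(rec <- readMolecules(sdfFile))
  expect_identical(nrow(rec), 2L)
  expect_true(all(rec$valid))
  expect_identical(deriveInchikey(rec$smiles[1]), deriveInchikey("CCO"))
})

test_that("InChIKeys are canonical, stereo-aware, standard-format", {
  key <- deriveInchikey("CCO")
  expect_identical(nchar(key), 27L)
  expect_identical(substr(key, 15, 15), "-")
  expect_identical(substr(key, 26, 26), "-")
  # equivalent SMILES share one key; stereoisomers do not
  expect_identical(deriveInchikey("OCC"), key)
  expect_false(deriveInchikey("F/C=C/F") == deriveInchikey("F/C=C\\F"))
  expect_true(is.na(deriveInchikey("not_a_smiles")))
})

test_that("descriptor matrices follow the documented column layout", {
  dm <- featurizeDataset("C", sefConfig("shannon_smiles"))
  expect_identical(unname(as.matrix(dm)), matrix(0, 1, 1))

  dm <- featurizeDataset("CCO", sefConfig(c("shannon_smiles", "frac_shannon"),
                                          nMax = 7))
  expect_identical(featureNames(dm),
                   c("shannon_smiles", sprintf("fse_%03d", 1:7)))
  expect_equal(unname(as.matrix(dm)[1, ]),
               c(ENT_2_1, 0, 0, c(2, 2, 1) / 3 * ENT_2_1, 0, 0),
               tolerance = 1e-12)

  dm <- featurizeDataset("C=CC", sefConfig("bond_freq"))
  expect_identical(unname(as.matrix(dm)[1, ]), c(0.5, 0.5, 0, 0, 0, 0, 0))

  dm <- featurizeDataset("CCO", sefConfig("mw"))
  expect_equal(unname(as.matrix(dm)[1, 1]), 46.068, tolerance = 1e-3)

  dm <- featurizeDataset("CCO", sefConfig("morgan", morganBits = 64))
  expect_identical(ncol(dm), 64L)
  expect_true(all(as.matrix(dm) %in% 0:1))

  expect_error(featurizeDataset("not_a_smiles", sefConfig("shannon_smiles")),
               "no valid records")
  expect_error(sefConfig(character(0)), "at least one feature family")
})

test_that("invalid records are excluded from rows but listed in provenance", {
  rec <- data.frame(id = c("a", "b"), smiles = c("CCO", "not_a_smiles"),
                    stringsAsFactors = FALSE)
  dm <- featurizeDataset(rec, sefConfig("shannon_smiles"))
  expect_identical(rownames(as.matrix(dm)), "a")
  expect_identical(dm@invalid$id, "b")
})

test_that("featurization is deterministic and batches share one padding width", {
  fx <- generateFixtures(20, seed = 3)
  cfg <- sefConfig()
  dm1 <- featurizeDataset(fx$records, cfg)
  dm2 <- featurizeDataset(fx$records, cfg)
  expect_identical(as.matrix(dm1), as.matrix(dm2))
  wide <- max(vapply(fx$records$smiles,
                     function(s) length(atomSpecies(s)), integer(1)))
  expect_identical(sum(grepl("^fse_", featureNames(dm1))), wide)
})

test_that("entropy-vs-MW correlation is computed and reported on fixtures", {
  fx <- generateFixtures(40, seed = 5)
  dm <- featurizeDataset(fx$records, sefConfig(c("mw", "shannon_smiles")))
  m <- as.matrix(dm)
  r <- abs(cor(m[, "shannon_smiles"], m[, "mw"]))
  # reported, not thresholded: the claim of low redundancy has no stated cut
  expect_true(is.finite(r) && r >= 0 && r <= 1)
})

test_that("one added atom perturbs entropy less than replacing half the atoms", {
  triples <- list(c(base = "CCCCCC", plusOne = "CCCCCCC", halfSwap = "CCCOOO"),
                  c(base = "CCCCO", plusOne = "CCCCCO", halfSwap = "CCNNO"),
                  c(base = "c1ccccc1", plusOne = "c1ccccc1C",
                    halfSwap = "c1ccccc1NNNN"))
  for (tr in triples) {
    s <- smilesEntropy(tr)
    expect_lt(abs(s[2] - s[1]), abs(s[3] - s[1]))
  }
})

test_that("node features carry mass, fractional entropy and bond weights", {
  nf <- atomNodeFeatures("C")
  expect_identical(nrow(nf$nodes), 1L)
  expect_equal(nf$nodes$mass, 12.011, tolerance = 1e-3)
  expect_identical(nf$nodes$fracEntropy, 0)
  expect_identical(nrow(nf$edges), 0L)

  nf <- atomNodeFeatures("CCO")
  expect_identical(nrow(nf$nodes), 3L)
  expect_identical(nrow(nf$edges), 2L)
  expect_identical(nf$edges$weight[1], nf$edges$weight[2])
  expect_identical(nf$nodes$totalEntropy, rep(smilesEntropy("CCO"), 3))

  # double vs single bond normalize to 1.0 and 0.5
  nf <- atomNodeFeatures("C=CC")
  expect_identical(nf$edges$weight, c(1, 0.5))
  expect_identical(nf$edges$from, c(0L, 1L))
})

test_that("descriptor CSVs round-trip losslessly with stable column order", {
  fx <- generateFixtures(8, seed = 9)
  dm <- featurizeDataset(fx$records, sefConfig())
  path <- tempfile(fileext = ".csv")
  writeDescriptors(dm, path)
  back <- readDescriptors(path)
  expect_equal(back, as.matrix(dm), tolerance = 1e-12)
  expect_identical(colnames(back), featureNames(dm))

  path2 <- tempfile(fileext = ".csv")
  writeDescriptors(dm, path2)
  expect_identical(readLines(path), readLines(path2))
})
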