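test_that("kNN with k = 1 has perfect memory and ties break stably", {
  fx <- generateFixtures(15, seed = 21)
  # dedup by structure: one molecule written as two SMILES would alias targets
  rec <- fx$records[!duplicated(deriveInchikey(fx$records$smiles)), ]
  fit <- knnPredict(rec$smiles, rec$target, rec$smiles, kSweep = 1L)
  expect_equal(fit$predictions, rec$target, tolerance = 1e-12)
  expect_identical(fit$bestK, 1L)

  # two identical training molecules, test equidistant, k = 2: the mean
  fit <- knnPredict(c("CCO", "CCO"), c(0, 1), "CCO", kSweep = 2L)
  expect_identical(fit$predictions, 0.5)

  # tie at the k-th rank resolves by training-set order
  fit <- knnPredict(c("CCO", "CCO", "CCC"), c(0, 1, 5), "CCO", kSweep = 1L)
  expect_identical(fit$predictions, 0)

  expect_error(knnPredict(character(0), numeric(0), "CCO"), "empty training")
  expect_error(knnPredict("CCO", 1, "CCO", kSweep = 5L), "k values")
})

test_that("kNN sweep picks a k from the sweep and classification votes", {
  fx <- generateFixtures(40, targetRule = "binary_threshold", seed = 22)
  rec <- fx$records
  fit <- knnPredict(rec$smiles[1:30], rec$target[1:30], rec$smiles[31:40],
                    task = "classification", seed = 4)
  expect_true(fit$bestK %in% 1:3)
  expect_true(all(fit$predictions %in% c(0, 1)))
  expect_identical(nrow(fit$sweep), 3L)
})

test_that("the RF grid search stays inside its declared grids", {
  fx <- generateFixtures(60, seed = 23)
  cfg <- sefConfig(c("shannon_smiles", "shannon_bonds", "bond_freq"))
  dm <- featurizeDataset(fx$records, cfg)
  x <- as.matrix(dm)
  half <- seq_len(30)
  fit <- rfFitPredict(x[half, ], fx$records$target[half], x[-half, ],
                      seed = 7)
  expect_true(fit$best$numTrees %in% c(25L, 100L, 200L))
  expect_true(fit$best$minLeaf %in% c(1L, 2L, 5L))
  expect_true(fit$best$minSplit %in% c(2L, 3L, 5L))
  expect_identical(nrow(fit$cvScores), 27L)

  # identical seed and inputs => identical predictions
  fit2 <- rfFitPredict(x[half, ], fx$records$target[half], x[-half, ],
                       seed = 7)
  expect_identical(fit$predictions, fit2$predictions)

  # constant training target => constant predictions
  cfit <- rfFitPredict(x[half, ], rep(3.5, 30), x[-half, ], seed = 1)
  expect_true(all(abs(cfit$predictions - 3.5) < 1e-12))

  colnames(x) <- NULL
  expect_error(rfFitPredict(as.matrix(dm)[half, ], fx$records$target[half],
                            x[-half, ]), "columns differ")
  expect_error(rfFitPredict(as.matrix(dm)[1:3, ], fx$records$target[1:3],
                            as.matrix(dm)), "fewer training rows")
  expect_error(rfFitPredict(as.matrix(dm)[half, ], fx$records$target[half],
                            as.matrix(dm), cvFolds = 3), "at least 5")
})

test_that("RF error shrinks as target noise shrinks", {
  maes <- vapply(c(0, 0.5, 2), function(sig) {
    fx <- generateFixtures(60, sigma = sig, seed = 31)
    dm <- featurizeDataset(fx$records,
                           sefConfig(c("shannon_smiles", "shannon_bonds")))
    x <- as.matrix(dm)
    tr <- seq_len(45)
    fit <- rfFitPredict(x[tr, ], fx$records$target[tr], x[-tr, ],
                        nTreesGrid = 100L, minLeafGrid = 1L,
                        minSplitGrid = 2L, seed = 2)
    evaluatePredictions(fit$predictions, fx$records$target[-tr])$mae
  }, numeric(1))
  expect_true(maes[1] < maes[2] && maes[2] < maes[3])
})

test_that("regression metrics follow their closed forms", {
  m <- evaluatePredictions(c(1, 2, 3), c(1, 2, 3))
  expect_identical(m$mape, 0)
  expect_identical(m$mae, 0)
  expect_identical(m$r2, 1)

  m <- evaluatePredictions(c(2, 2, 2, 2), c(1, 1, 1, 1))
  expect_identical(m$mape, 100)
  expect_identical(m$mae, 1)
  expect_true(m$r2Undefined)
  expect_true(is.na(m$r2))

  # zero truths are excluded from MAPE and counted
  m <- evaluatePredictions(c(1, 2), c(0, 1))
  expect_identical(m$nZeroExcluded, 1L)
  expect_identical(m$mape, 100)

  expect_error(evaluatePredictions(1:3, 1:2), "differ in length")
})

test_that("classification metrics and the rank-statistic AUC are standard", {
  m <- evaluatePredictions(c(0.1, 0.9), c(0, 1), task = "classification")
  expect_identical(m$rocAuc, 1)
  expect_identical(m$accuracy, 1)

  # permutation invariance and cross-check against an independent AUC
  set.seed(8)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.4)
  m <- evaluatePredictions(scores, labels, task = "classification")
  perm <- sample(60)
  m2 <- evaluatePredictions(scores[perm], labels[perm],
                            task = "classification")
  expect_identical(m$rocAuc, m2$rocAuc)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(m$rocAuc, ref, tolerance = 1e-12)
})

test_that("replicate summaries average each metric over the runs", {
  reps <- lapply(1:5, function(i)
    evaluatePredictions(c(1, 2, 3) + i * 0.1, c(1, 2, 3)))
  s <- summarizeReplicates(reps)
  expect_identical(s$replicates, 5L)
  expect_equal(unname(s$mean[["mae"]]), 0.3, tolerance = 1e-12)
  expect_true(all(c("mae", "rmse", "r2") %in% names(s$mean)))
})
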