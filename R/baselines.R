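#' @include featurize.R
NULL

#' Tanimoto similarity between fingerprint matrices
#'
#' \eqn{|A \cap B| / |A \cup B|} over the set bits of each row pair.
#' Rows with no set bits have undefined similarity (NA).
#'
#' @param fpA,fpB 0/1 matrices with one fingerprint per row
#' @return \code{nrow(fpA)} x \code{nrow(fpB)} similarity matrix.
#' @export
tanimotoSimilarity <- function(fpA, fpB) {
  fpA <- as.matrix(fpA); fpB <- as.matrix(fpB)
  inter <- fpA %*% t(fpB)
  nA <- rowSums(fpA); nB <- rowSums(fpB)
  union <- outer(nA, nB, "+") - inter
  sim <- inter / union
  sim[union == 0] <- NA_real_
  sim
}

.knnFromSim <- function(sim, trainY, k, task) {
  apply(sim, 1L, function(s) {
    if (all(is.na(s))) return(NA_real_)
    # stable order: ties at the k-th rank resolved by training-set position
    ord <- order(-s, seq_along(s))
    nb <- ord[seq_len(min(k, length(ord)))]
    if (task == "regression") {
      mean(trainY[nb])
    } else {
      votes <- tapply(s[nb], trainY[nb], length)
      if (length(votes) == 1L) return(as.numeric(names(votes)[1L]))
      top <- votes == max(votes)
      if (sum(top) == 1L) return(as.numeric(names(votes)[which(top)]))
      # tie: the class of the more similar neighbour wins
      as.numeric(trainY[nb[1L]])
    }
  })
}

#' Tanimoto-similarity k-nearest-neighbour predictor
#'
#' Predicts each test molecule's property as the mean target (majority
#' vote for classification, ties broken toward the more similar neighbour)
#' of its k most Tanimoto-similar training molecules, with similarity over
#' ECFP4 fingerprints. The values of k in \code{kSweep} are compared on a
#' held-out validation split of the training set (lowest MAE for
#' regression, highest accuracy for classification) and the best k is used
#' to predict the test set from the full training set. Ties in similarity
#' at the k-th rank are resolved by stable training-set order.
#'
#' Molecules whose fingerprint has no set bits have undefined similarity;
#' their predictions are returned NA and flagged.
#'
#' @param trainSmiles,trainY training molecules and targets (numeric, or
#'   0/1 labels for classification)
#' @param testSmiles molecules to predict
#' @param kSweep candidate neighbourhood sizes (default 1, 2, 3)
#' @param task \code{"regression"} or \code{"classification"}
#' @param valFraction fraction of the training set held out to choose k
#'   (default 0.2; the sweep is skipped when only one k is given)
#' @param seed seed for the validation split
#' @return List with \code{predictions}, \code{bestK}, \code{sweep} (the
#'   validation score per k) and \code{flagged} (indices of NA
#'   predictions).
#' @export
knnPredict <- function(trainSmiles, trainY, testSmiles, kSweep = c(1L, 2L, 3L),
                       task = c("regression", "classification"),
                       valFraction = 0.2, seed = 1L) {
  task <- match.arg(task)
  n <- length(trainSmiles)
  if (n == 0L) stop("empty training set", call. = FALSE)
  stopifnot(length(trainY) == n)
  kSweep <- sort(unique(as.integer(kSweep)))
  if (any(kSweep < 1L) || any(kSweep > n))
    stop("k values must be in 1..n_train", call. = FALSE)

  fpTrain <- morganFingerprint(trainSmiles, bits = 4096L)
  fpTest <- morganFingerprint(testSmiles, bits = 4096L)

  sweep <- NULL
  bestK <- kSweep[1L]
  if (length(kSweep) > 1L) {
    nVal <- max(1L, floor(valFraction * n))
    if (n - nVal >= max(kSweep)) {
      set.seed(seed)
      valIdx <- sample.int(n, nVal)
      simVal <- tanimotoSimilarity(fpTrain[valIdx, , drop = FALSE],
                                   fpTrain[-valIdx, , drop = FALSE])
      yFit <- trainY[-valIdx]
      yVal <- trainY[valIdx]
      score <- vapply(kSweep, function(k) {
        p <- .knnFromSim(simVal, yFit, k, task)
        keep <- !is.na(p)
        if (!any(keep)) return(NA_real_)
        if (task == "regression") mean(abs(p[keep] - yVal[keep]))
        else -mean((p[keep] > 0.5) == (yVal[keep] > 0.5))
      }, numeric(1))
      sweep <- data.frame(k = kSweep,
                          score = if (task == "regression") score else -score)
      bestK <- kSweep[which.min(score)]
    }
  }

  sim <- tanimotoSimilarity(fpTest, fpTrain)
  pred <- .knnFromSim(sim, trainY, bestK, task)
  list(predictions = unname(pred), bestK = bestK, sweep = sweep,
       flagged = which(is.na(pred)))
}

#' Grid-searched random forest fit and prediction
#'
#' Evaluates the full hyperparameter grid — number of trees, minimum
#' samples per leaf, minimum samples to split (defaults 25/100/200, 1/2/5
#' and 2/3/5) — by k-fold cross-validation on the training set (at least 5
#' folds), refits the best combination on all of the training data, and
#' predicts the test set. Selection is by CV mean squared error for
#' regression and CV misclassification rate for classification. The whole
#' procedure is reproducible under \code{seed}.
#'
#' @param trainX,trainY training features (matrix or
#'   \linkS4class{DescriptorMatrix}) and targets; a factor \code{trainY}
#'   switches to classification
#' @param testX test features with identical columns
#' @param nTreesGrid,minLeafGrid,minSplitGrid the hyperparameter grids
#' @param cvFolds number of cross-validation folds (minimum 5)
#' @param seed integer seed controlling fold assignment and tree growth
#' @return List with \code{predictions}, \code{best} (the chosen
#'   hyperparameter triple) and \code{cvScores} (the full grid with CV
#'   scores).
#' @export
rfFitPredict <- function(trainX, trainY, testX,
                         nTreesGrid = c(25L, 100L, 200L),
                         minLeafGrid = c(1L, 2L, 5L),
                         minSplitGrid = c(2L, 3L, 5L),
                         cvFolds = 5L, seed = 1L) {
  if (is(trainX, "DescriptorMatrix")) trainX <- trainX@values
  if (is(testX, "DescriptorMatrix")) testX <- testX@values
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  if (!identical(colnames(trainX), colnames(testX)))
    stop("train and test feature columns differ", call. = FALSE)
  n <- nrow(trainX)
  cvFolds <- as.integer(cvFolds)
  if (cvFolds < 5L) stop("cvFolds must be at least 5", call. = FALSE)
  if (n < cvFolds)
    stop("fewer training rows (", n, ") than cvFolds (", cvFolds, ")",
         call. = FALSE)
  classify <- is.factor(trainY)

  grid <- expand.grid(numTrees = as.integer(nTreesGrid),
                      minLeaf = as.integer(minLeafGrid),
                      minSplit = as.integer(minSplitGrid))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(cvFolds), n))

  fitOne <- function(x, y, g, s) {
    ranger::ranger(x = x, y = y, num.trees = g$numTrees,
                   min.bucket = g$minLeaf, min.node.size = g$minSplit,
                   seed = s, num.threads = 1L)
  }
  score <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    errs <- numeric(cvFolds)
    for (fd in seq_len(cvFolds)) {
      inFold <- fold == fd
      fit <- fitOne(trainX[!inFold, , drop = FALSE], trainY[!inFold],
                    grid[gi, ], seed + fd)
      p <- stats::predict(fit, data = trainX[inFold, , drop = FALSE])$predictions
      errs[fd] <- if (classify) mean(p != trainY[inFold])
                  else mean((p - trainY[inFold])^2)
    }
    score[gi] <- mean(errs)
  }
  bestIdx <- which.min(score)
  best <- grid[bestIdx, ]
  finalFit <- fitOne(trainX, trainY, best, seed)
  pred <- stats::predict(finalFit, data = testX)$predictions
  list(predictions = pred,
       best = list(numTrees = best$numTrees, minLeaf = best$minLeaf,
                   minSplit = best$minSplit),
       cvScores = cbind(grid, cvScore = score))
}

.rocAuc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Standard QSAR evaluation metrics
#'
#' Regression: MAPE (\eqn{100 \cdot \mathrm{mean}(|(y-\hat y)/y|)}, rows
#' with zero truth excluded and counted), MAE, RMSE, and
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (NA with a flag when all truths are
#' equal). Classification: ROC AUC by the rank statistic over scores, and
#' accuracy at a 0.5 threshold. All metrics are invariant to a common
#' permutation of the prediction/truth pairs.
#'
#' @param predictions,truths equal-length numeric vectors (scores and 0/1
#'   labels for classification)
#' @param task \code{"regression"} or \code{"classification"}
#' @return Named list of metrics plus \code{n}; regression lists
#'   \code{nZeroExcluded}, and \code{r2Undefined} flags a zero-variance
#'   truth vector.
#' @export
#' @examples
#' evaluatePredictions(c(2, 2), c(1, 1))  # MAPE 100, MAE 1
evaluatePredictions <- function(predictions, truths,
                                task = c("regression", "classification")) {
  task <- match.arg(task)
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length", call. = FALSE)
  if (length(truths) < 1L) stop("empty input", call. = FALSE)
  if (task == "regression") {
    err <- predictions - truths
    nz <- truths != 0
    mape <- if (any(nz)) 100 * mean(abs(err[nz] / truths[nz])) else NA_real_
    sstot <- sum((truths - mean(truths))^2)
    r2 <- if (sstot == 0) NA_real_ else 1 - sum(err^2) / sstot
    list(mape = mape, mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
         r2 = r2, r2Undefined = sstot == 0,
         nZeroExcluded = sum(!nz), n = length(truths))
  } else {
    list(rocAuc = .rocAuc(predictions, truths),
         accuracy = mean((predictions > 0.5) == (truths > 0.5)),
         n = length(truths))
  }
}

#' Average a metric report over independent replicate runs
#'
#' Stochastic models are reported as the mean and standard deviation of
#' each metric over at least five independent runs; this helper folds a
#' list of [evaluatePredictions()] reports into that summary.
#'
#' @param reports a list of metric lists from [evaluatePredictions()]
#' @return A list with \code{mean}, \code{sd} (named numeric vectors over
#'   the shared numeric metrics) and \code{replicates}.
#' @export
summarizeReplicates <- function(reports) {
  stopifnot(length(reports) >= 1L)
  keys <- names(reports[[1L]])
  keys <- keys[vapply(reports[[1L]], is.numeric, logical(1))]
  vals <- vapply(reports, function(r) unlist(r[keys]), numeric(length(keys)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(keys))
  rownames(vals) <- keys
  list(mean = rowMeans(vals),
       sd = apply(vals, 1L, stats::sd),
       replicates = length(reports))
}
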