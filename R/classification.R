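## Position separation: binary pattern-presence features, five classifiers
## under shuffled 10-fold cross-validation, and coefficient-based
## importance ranking.

.CLASSIFIERS <- c("DecisionTree", "GaussianNaiveBayes", "RandomForest",
                  "LogisticRegression", "MLP")

#' Build the binary pattern-presence feature matrix
#'
#' One row (column of the assay) per player-match observation, one feature
#' per unique pattern of the union; the entry is 1 when that observation's
#' mined pattern set contains the pattern, 0 otherwise. Labels are the
#' positions carried by the corpora.
#'
#' @param patternSets list of per-corpus \linkS4class{PatternSet}s, one per
#'   observation, all of the union's algorithm.
#' @param un the \linkS4class{PatternUnion} defining the feature columns
#'   (defaults to the union of \code{patternSets}).
#' @return A \code{SummarizedExperiment}: assay \code{"presence"} is the
#'   patterns x observations 0/1 matrix, \code{rowData} holds the pattern
#'   items, \code{colData} the \code{player_id}, \code{match_id} and
#'   \code{position} of each observation, and
#'   \code{metadata()$algorithm} the algorithm tag.
#' @export
buildFeatureMatrix <- function(patternSets, un = unionPatternSets(patternSets)) {
  stopifnot(length(patternSets) > 0L, is(un, "PatternUnion"))
  tags <- unique(vapply(patternSets, algorithmTag, character(1L)))
  if (length(tags) != 1L || !identical(tags, un@algorithm)) {
    stop("pattern sets and union must come from the same algorithm")
  }
  feats <- un@patterns$items
  mat <- vapply(patternSets, function(ps) {
    as.integer(feats %in% ps@patterns$items)
  }, integer(length(feats)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(feats))
  obs <- sprintf("%s.%s",
                 vapply(patternSets, playerId, character(1L)),
                 vapply(patternSets, matchId, character(1L)))
  dimnames(mat) <- list(feats, make.unique(obs))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = mat),
    rowData = S4Vectors::DataFrame(items = feats),
    colData = S4Vectors::DataFrame(
      player_id = vapply(patternSets, playerId, character(1L)),
      match_id = vapply(patternSets, matchId, character(1L)),
      position = vapply(patternSets, positionLabel, character(1L)),
      row.names = make.unique(obs)),
    metadata = list(algorithm = un@algorithm)
  )
}

## one fitted prediction, dispatching on classifier name
.fitPredict <- function(name, xtr, ytr, xte, mlpSize = 8L) {
  lev <- levels(ytr)
  pred <- switch(
    name,
    DecisionTree = {
      ## unrestricted tree growth, mirroring the usual library default of
      ## splitting down to pure leaves without pruning
      df <- as.data.frame(xtr)
      df$.y <- ytr
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 2L,
                                                         minbucket = 1L,
                                                         cp = 0, xval = 0L))
      as.character(predict(fit, newdata = as.data.frame(xte),
                           type = "class"))
    },
    GaussianNaiveBayes = {
      ## binary presence features are often constant within a class; floor
      ## the per-class sd (variance-smoothing) and clamp vanished densities
      ## so the log-likelihood stays finite instead of collapsing
      fit <- e1071::naiveBayes(xtr, ytr)
      smooth <- sqrt(1e-9 * max(vapply(fit$tables,
                                       function(tb) max(tb[, 2L]^2, 0,
                                                        na.rm = TRUE),
                                       numeric(1L)), 0.25))
      fit$tables <- lapply(fit$tables, function(tb) {
        tb[, 2L] <- pmax(tb[, 2L], smooth, na.rm = TRUE)
        tb
      })
      as.character(predict(fit, xte, eps = 1e-300, threshold = 1e-300))
    },
    RandomForest = {
      set.seed(1L)
      fit <- randomForest::randomForest(xtr, ytr)
      as.character(predict(fit, xte))
    },
    LogisticRegression = {
      allConst <- all(vapply(seq_len(ncol(xtr)), function(j) {
        all(xtr[, j] == xtr[1L, j])
      }, logical(1L)))
      if (allConst) {
        ## intercept-only model: the majority class
        rep(names(which.max(table(ytr))), nrow(xte))
      } else {
        fit <- .glmnetL1(.atLeastTwoCols(xtr), ytr)
        as.character(predict(fit, .atLeastTwoCols(xte),
                             type = "class")[, 1L])
      }
    },
    MLP = {
      set.seed(5L)
      fit <- nnet::nnet(x = xtr, y = nnet::class.ind(ytr), size = mlpSize,
                        softmax = TRUE, maxit = 300L, trace = FALSE,
                        MaxNWts = 1e7)
      pr <- predict(fit, xte)
      colnames(nnet::class.ind(ytr))[max.col(pr, ties.method = "first")]
    },
    stop("unknown classifier: ", name)
  )
  factor(pred, levels = lev)
}

## glmnet needs >= 2 columns; pad with an all-zero dummy if needed
.atLeastTwoCols <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, .dummy = 0)
}

## L1 logistic fit at the per-observation penalty weight; small training
## folds trigger a purely advisory class-size warning, which is muffled
.glmnetL1 <- function(x, y) {
  withCallingHandlers(
    glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                   lambda = 1 / nrow(x), standardize = FALSE),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

## accuracy / precision / recall / F1 with class averaging
.predMetrics <- function(truth, pred, average = c("weighted", "macro")) {
  average <- match.arg(average)
  lev <- levels(truth)
  cm <- table(factor(truth, lev), factor(pred, lev))
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- if (average == "weighted") {
    support / sum(support)
  } else {
    rep(1 / length(lev), length(lev))
  }
  c(accuracy = sum(tp) / sum(cm),
    precision = sum(w * prec), recall = sum(w * rec), f1 = sum(w * f1))
}

#' Cross-validated position classification on pattern presence
#'
#' Fits the study's five classifiers -- decision tree, Gaussian naive
#' Bayes, random forest (seed 1), L1-penalised logistic regression, and a
#' multi-layer perceptron (300 iterations, seed 5) -- under plain shuffled
#' k-fold cross-validation (no stratification; fold shuffle seed 10 by
#' default) and reports per-fold and fold-averaged accuracy, precision,
#' recall and F1. Precision/recall/F1 are averaged over the two classes,
#' weighted by class support by default (\code{average = "macro"} gives the
#' unweighted mean).
#'
#' @param fm feature matrix from [buildFeatureMatrix()].
#' @param classifiers subset of
#'   \code{c("DecisionTree", "GaussianNaiveBayes", "RandomForest",
#'   "LogisticRegression", "MLP")}.
#' @param folds number of folds (default 10).
#' @param shuffleSeed seed for the fold shuffle (default 10).
#' @param average class-averaging rule for precision/recall/F1.
#' @param mlpSize hidden-layer width of the perceptron (default 8).
#' @return A list: \code{aggregate} (data.frame of fold-mean metrics per
#'   classifier), \code{folds} (per-fold metrics) and \code{algorithm}.
#' @export
runCrossValidation <- function(fm, classifiers = .CLASSIFIERS, folds = 10L,
                               shuffleSeed = 10L,
                               average = c("weighted", "macro"),
                               mlpSize = 8L) {
  average <- match.arg(average)
  classifiers <- match.arg(classifiers, .CLASSIFIERS, several.ok = TRUE)
  x <- t(SummarizedExperiment::assay(fm, "presence"))
  storage.mode(x) <- "double"
  colnames(x) <- sprintf("f%06d", seq_len(ncol(x)))
  y <- factor(fm$position)
  n <- nrow(x)
  if (nlevels(y) < 2L) stop("both position labels must be present")
  if (nlevels(y) != 2L) stop("exactly two position labels are supported")
  if (n < folds) stop("need at least as many observations as folds")
  set.seed(as.integer(shuffleSeed))
  perm <- sample.int(n)
  foldId <- integer(n)
  foldId[perm] <- rep(seq_len(folds), length.out = n)
  foldRows <- list()
  for (cls in classifiers) {
    for (fd in seq_len(folds)) {
      te <- foldId == fd
      m <- .predMetrics(y[te],
                        .fitPredict(cls, x[!te, , drop = FALSE], y[!te],
                                    x[te, , drop = FALSE],
                                    mlpSize = mlpSize),
                        average = average)
      foldRows[[length(foldRows) + 1L]] <-
        data.frame(classifier = cls, fold = fd, t(m))
    }
  }
  folds_df <- do.call(rbind, foldRows)
  agg <- do.call(rbind, lapply(split(folds_df, folds_df$classifier), function(d) {
    data.frame(classifier = d$classifier[1L],
               accuracy = mean(d$accuracy), precision = mean(d$precision),
               recall = mean(d$recall), f1 = mean(d$f1))
  }))
  agg <- agg[match(classifiers, agg$classifier), , drop = FALSE]
  rownames(agg) <- rownames(folds_df) <- NULL
  list(aggregate = agg, folds = folds_df,
       algorithm = S4Vectors::metadata(fm)$algorithm)
}

#' Rank features by importance score
#'
#' Importance is the absolute value of the supplied (signed) coefficients;
#' features are ordered by decreasing importance with lexicographic
#' tie-breaks and truncated to the top \code{topN}.
#'
#' @param coefficients numeric vector, one per pattern.
#' @param patterns character vector of pattern items, parallel to
#'   \code{coefficients}.
#' @param topN ranking length (default 20).
#' @return data.frame with columns \code{rank}, \code{pattern},
#'   \code{score} (non-increasing).
#' @export
rankImportance <- function(coefficients, patterns, topN = 20L) {
  if (length(coefficients) != length(patterns)) {
    stop("one coefficient per pattern is required")
  }
  score <- abs(coefficients)
  ord <- order(-score, patterns)
  ord <- utils::head(ord, topN)
  data.frame(rank = seq_along(ord), pattern = patterns[ord],
             score = score[ord], stringsAsFactors = FALSE)
}

#' Top patterns by L1 logistic-regression coefficient magnitude
#'
#' Fits the L1-penalised logistic model on the full feature matrix and
#' ranks patterns by absolute coefficient, mirroring the importance
#' analysis applied to the linear classifier.
#'
#' @param fm feature matrix from [buildFeatureMatrix()].
#' @param topN ranking length (default 20).
#' @return data.frame as in [rankImportance()].
#' @export
logisticImportance <- function(fm, topN = 20L) {
  x <- t(SummarizedExperiment::assay(fm, "presence"))
  storage.mode(x) <- "double"
  feats <- colnames(x)
  colnames(x) <- sprintf("f%06d", seq_len(ncol(x)))
  y <- factor(fm$position)
  fit <- .glmnetL1(.atLeastTwoCols(x), y)
  co <- as.numeric(stats::coef(fit))[-1L][seq_along(feats)]
  rankImportance(co, feats, topN = topN)
}
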