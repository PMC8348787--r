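# The five classifier configurations evaluated by the harness, mirroring
# the WEKA setups they originate from: 1-nearest-neighbour with Manhattan
# distance, a depth-limited decision tree, a 100-tree random forest,
# grow/prune rule induction, and 100-round gradient boosted trees.
#
# Standard learners are delegated to rpart, ranger and xgboost. Manhattan
# KNN and the grow/prune rule inducer have no installed equivalent and are
# implemented here: KNN as an exact brute-force neighbour search, the rule
# inducer as a reduced-error-pruned tree (grown on the "grow" share of the
# training rows, pruned to the complexity that minimises error on the
# held-out "prune" share — each root-to-leaf path acting as one rule).

#' Classifier configuration
#'
#' One of the five supported classifier kinds with hyperparameter defaults
#' mirroring the reference configurations: `knn` (K = 1, Manhattan
#' distance), `j48` (decision tree, max depth 50), `rf` (random forest,
#' 100 trees), `ir` (induction rules, grow/prune ratio 0.95) and `gbt`
#' (gradient boosted trees, 100 trees, depth 50).
#'
#' @param kind one of `"knn"`, `"j48"`, `"rf"`, `"ir"`, `"gbt"`.
#' @param k neighbours for `knn` (default 1).
#' @param max_depth tree depth cap for `j48`/`gbt` (default 50; the rpart
#'   engine behind `j48` supports at most 30 and is capped there).
#' @param n_trees ensemble size for `rf`/`gbt` (default 100).
#' @param grow_ratio share of training rows used for rule growing in `ir`
#'   (default 0.95; the remainder drives reduced-error pruning).
#' @param seed integer seed for the classifier's own randomness.
#' @return An object of class `classifier_config`.
#' @export
#' @examples
#' classifier_config("rf")
classifier_config <- function(kind = c("knn", "j48", "rf", "ir", "gbt"),
                              k = 1L, max_depth = 50L, n_trees = 100L,
                              grow_ratio = 0.95, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(k >= 1, max_depth >= 1, n_trees >= 1,
            grow_ratio > 0, grow_ratio < 1)
  structure(
    list(kind = kind, k = as.integer(k), max_depth = as.integer(max_depth),
         n_trees = as.integer(n_trees), grow_ratio = grow_ratio,
         seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' @export
print.classifier_config <- function(x, ...) {
  cfgtxt <- switch(x$kind,
    knn = sprintf("K = %d, Manhattan distance", x$k),
    j48 = sprintf("max depth = %d", x$max_depth),
    rf  = sprintf("%d trees", x$n_trees),
    ir  = sprintf("grow/prune ratio = %g", x$grow_ratio),
    gbt = sprintf("%d trees, depth = %d", x$n_trees, x$max_depth))
  cat(sprintf("<classifier_config> %s (%s)\n", toupper(x$kind), cfgtxt))
  invisible(x)
}

# exact brute-force K-NN with Manhattan (L1) metric; ties on distance and
# on the vote both resolve to the first (lowest-index) candidate
knn_manhattan_predict <- function(train_x, train_y, test_x, k = 1L) {
  tx <- t(train_x)  # p x n_train; column-wise recycling below
  n_test <- nrow(test_x)
  out <- character(n_test)
  lev <- levels(train_y)
  for (i in seq_len(n_test)) {
    d <- colSums(abs(tx - test_x[i, ]))
    if (k == 1L) {
      out[i] <- as.character(train_y[which.min(d)])
    } else {
      nn <- order(d)[seq_len(k)]
      votes <- table(train_y[nn])
      out[i] <- names(votes)[which.max(votes)]
    }
  }
  factor(out, levels = lev)
}

fit_classifier <- function(clf, x, y, seed = clf$seed) {
  stopifnot(inherits(clf, "classifier_config"), is.factor(y),
            nrow(x) == length(y))
  x <- as.matrix(x)
  model <- switch(
    clf$kind,
    knn = list(train_x = x, train_y = y, k = clf$k),
    j48 = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = min(clf$max_depth, 30L),
                     cp = 0, minsplit = 2L, xval = 0))
    },
    rf = ranger::ranger(x = x, y = y, num.trees = clf$n_trees,
                        num.threads = 1L, seed = seed),
    ir = withr::with_seed(seed, {
      n <- nrow(x)
      grow_idx <- sort(sample.int(n, max(2L, floor(clf$grow_ratio * n))))
      prune_idx <- setdiff(seq_len(n), grow_idx)
      df <- data.frame(.y = y, x, check.names = FALSE)
      full <- rpart::rpart(.y ~ ., data = df[grow_idx, , drop = FALSE],
                           method = "class",
                           control = rpart::rpart.control(
                             maxdepth = 30L, cp = 0, minsplit = 2L, xval = 0))
      if (length(prune_idx) >= 1) {
        cps <- full$cptable[, "CP"]
        errs <- vapply(cps, function(cp) {
          pr <- rpart::prune(full, cp = cp)
          mean(predict(pr, df[prune_idx, , drop = FALSE],
                       type = "class") != y[prune_idx])
        }, 0)
        rpart::prune(full, cp = cps[which.min(errs)])
      } else full
    }),
    gbt = {
      lev <- levels(y)
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      booster <- xgboost::xgb.train(
        params = list(objective = "multi:softmax",
                      num_class = length(lev),
                      max_depth = clf$max_depth,
                      eta = 0.3,
                      tree_method = "hist",
                      nthread = 1L,
                      seed = seed),
        data = dtrain, nrounds = clf$n_trees, verbose = 0)
      list(booster = booster, levels = lev)
    }
  )
  structure(list(clf = clf, model = model, levels = levels(y)),
            class = "mpar_classifier")
}

predict_classifier <- function(fit, x) {
  stopifnot(inherits(fit, "mpar_classifier"))
  x <- as.matrix(x)
  switch(
    fit$clf$kind,
    knn = knn_manhattan_predict(fit$model$train_x, fit$model$train_y, x,
                                k = fit$clf$k),
    j48 = ,
    ir = {
      df <- as.data.frame(x)
      factor(as.character(predict(fit$model, df, type = "class")),
             levels = fit$levels)
    },
    rf = factor(as.character(
           predict(fit$model, data = x, num.threads = 1L,
                   seed = 1L)$predictions),
           levels = fit$levels),
    gbt = {
      pred <- predict(fit$model$booster, xgboost::xgb.DMatrix(x))
      factor(fit$model$levels[as.integer(pred) + 1L], levels = fit$levels)
    }
  )
}
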