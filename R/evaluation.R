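# Repeated random train-test evaluation of window-level feature tables.
#
# The protocol: pool all windows, split at 90-10 / 80-20 / 70-30, fit a
# classifier configuration on the training share, score the disjoint test
# share, repeat with fresh random splits, and report the mean accuracy
# together with the accumulated confusion matrix. Splits are stratified by
# activity class by default (ten imbalanced classes make small unstratified
# test sets noisy); an unstratified mode is available.

#' Split plan for repeated random evaluation
#'
#' @param train_fraction fraction of rows used for training; one of 0.90,
#'   0.80, 0.70 in the standard protocol (other values in (0, 1) are
#'   accepted).
#' @param repeats number of independent random splits (default 10).
#' @param seed master integer seed; all split randomness derives from it.
#' @param stratified preserve class proportions within one row per class
#'   (default `TRUE`).
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(train_fraction = 0.8, repeats = 10L, seed = 1L,
                       stratified = TRUE) {
  stopifnot(train_fraction > 0, train_fraction < 1, repeats >= 1)
  structure(
    list(train_fraction = train_fraction, repeats = as.integer(repeats),
         seed = as.integer(seed), stratified = isTRUE(stratified)),
    class = "split_plan"
  )
}

# deterministic per-repeat seed stream, kept inside 32-bit integer range
derive_seed <- function(seed, repeat_index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + repeat_index * 7919 + salt * 104729) %%
               2147483647)
}

#' Split a feature table into disjoint train and test sets
#'
#' Deterministic given `(plan$seed, repeat_index)`. The training set size
#' is `round(train_fraction * nrow(table))` exactly; in stratified mode the
#' per-class training counts follow a largest-remainder allocation of that
#' total, so each class's train share is within one row of
#' `train_fraction` while every class keeps at least one train and one
#' test row.
#'
#' @param table a feature table (data.frame with an `activity_label`
#'   column).
#' @param plan a [split_plan()].
#' @param repeat_index which repeat (1-based) this split belongs to.
#' @return List with elements `train`, `test` (row subsets of `table`) and
#'   `train_idx`, `test_idx` (the row indices).
#' @export
split_table <- function(table, plan, repeat_index = 1L) {
  stopifnot(inherits(plan, "split_plan"), nrow(table) >= 2)
  n <- nrow(table)
  n_train <- round(plan$train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  rs <- derive_seed(plan$seed, repeat_index)
  train_idx <- withr::with_seed(rs, {
    if (!plan$stratified) {
      sort(sample.int(n, n_train))
    } else {
      cls <- as.character(table$activity_label)
      counts <- base::table(cls)
      if (any(counts < 2)) {
        stop("stratified split needs >= 2 rows per class; offending class: ",
             paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
      }
      targets <- plan$train_fraction * as.numeric(counts)
      base <- pmax(1L, pmin(as.integer(counts) - 1L, floor(targets)))
      rem <- n_train - sum(base)
      if (rem > 0) {
        # largest remainders first, capped at n_c - 1 per class
        ord <- order(targets - floor(targets), decreasing = TRUE)
        for (j in ord) {
          if (rem == 0) break
          room <- (as.integer(counts)[j] - 1L) - base[j]
          add <- min(room, rem)
          base[j] <- base[j] + add
          rem <- rem - add
        }
      } else if (rem < 0) {
        ord <- order(targets - floor(targets))
        for (j in ord) {
          if (rem == 0) break
          slack <- base[j] - 1L
          take <- min(slack, -rem)
          base[j] <- base[j] - take
          rem <- rem + take
        }
      }
      idx <- unlist(lapply(seq_along(counts), function(j) {
        rows <- which(cls == names(counts)[j])
        sample(rows, base[j])
      }))
      sort(idx)
    }
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Train a classifier over repeated splits and evaluate it
#'
#' For each repeat: split the table per the plan, fit the classifier
#' configuration on the training rows' 43 feature columns, predict the
#' disjoint test rows, and accumulate the accuracy and the
#' true-by-predicted confusion counts. All randomness (splits and any
#' classifier-internal randomness) derives from `plan$seed`, so a rerun
#' with the same arguments reproduces the result exactly.
#'
#' @param table a feature table with >= 2 classes.
#' @param clf a [classifier_config()].
#' @param plan a [split_plan()].
#' @param class_levels optional explicit class ordering for the confusion
#'   matrix; defaults to the MPA vocabulary order for MPA labels, sorted
#'   unique labels otherwise.
#' @return An object of class `eval_result`: `accuracies` (per repeat),
#'   `mean_accuracy`, `confusion` (counts summed over repeats, rows = true
#'   class, columns = predicted), `per_class_recall`, plus the `clf` and
#'   `plan` used.
#' @export
train_and_evaluate <- function(table, clf, plan, class_levels = NULL) {
  stopifnot(inherits(clf, "classifier_config"), inherits(plan, "split_plan"))
  labs <- as.character(table$activity_label)
  if (is.null(class_levels)) {
    mpa <- names(activity_labels())
    class_levels <- if (all(labs %in% mpa)) {
      mpa[mpa %in% labs]
    } else {
      sort(unique(labs))
    }
  }
  if (length(class_levels) < 2) stop("need >= 2 classes", call. = FALSE)
  fn <- feature_names()
  xmat <- as.matrix(table[, fn])
  y <- factor(labs, levels = class_levels)
  conf <- matrix(0L, length(class_levels), length(class_levels),
                 dimnames = list(true = class_levels, predicted = class_levels))
  accs <- numeric(plan$repeats)
  for (r in seq_len(plan$repeats)) {
    sp <- split_table(table, plan, r)
    fit <- fit_classifier(clf, xmat[sp$train_idx, , drop = FALSE],
                          y[sp$train_idx],
                          seed = derive_seed(plan$seed, r, salt = 1L))
    pred <- predict_classifier(fit, xmat[sp$test_idx, , drop = FALSE])
    truth <- y[sp$test_idx]
    conf <- conf + unclass(base::table(truth, pred))
    accs[r] <- mean(pred == truth)
  }
  total <- sum(conf)
  structure(
    list(clf = clf, plan = plan,
         accuracies = accs,
         mean_accuracy = mean(accs),
         confusion = conf,
         per_class_recall = diag(conf) / rowSums(conf),
         n_test_total = total),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, digits = 3, ...) {
  cat(sprintf("<eval_result> %s, train fraction %.2f, %d repeats\n",
              toupper(x$clf$kind), x$plan$train_fraction, x$plan$repeats))
  cat(sprintf("  mean accuracy %.*f (per-repeat sd %.*f), %d test windows\n",
              digits, x$mean_accuracy, digits, stats::sd(x$accuracies),
              x$n_test_total))
  invisible(x)
}

#' Row-normalise a confusion matrix to per-class percentages
#'
#' @param conf a counts confusion matrix (rows = true class).
#' @return Matrix of row percentages (each row sums to 100 for non-empty
#'   rows).
#' @export
confusion_percent <- function(conf) {
  rs <- rowSums(conf)
  sweep(conf, 1, ifelse(rs > 0, rs, 1), "/") * 100
}

#' Evaluate the full window-config x classifier x split grid
#'
#' Runs [train_and_evaluate()] over the Cartesian product of the supplied
#' feature tables (one per windowing configuration), classifier
#' configurations and split plans. Each grid cell is computed exactly as a
#' standalone [train_and_evaluate()] call with the same seed would compute
#' it.
#'
#' @param tables named list of feature tables, e.g.
#'   `list("w1_overlap" = ..., "w1_abut" = ...)`.
#' @param classifiers list of [classifier_config()] objects.
#' @param plans list of [split_plan()] objects.
#' @return An object of class `mpar_grid`: `results` (list keyed
#'   `<table>.<classifier>.<train pct>`) and `summary` (data.frame with one
#'   row per cell: table, classifier, train_fraction, mean_accuracy).
#' @export
run_grid <- function(tables, classifiers, plans) {
  stopifnot(length(tables) >= 1, length(classifiers) >= 1, length(plans) >= 1)
  if (is.null(names(tables))) names(tables) <- paste0("table", seq_along(tables))
  results <- list()
  rows <- list()
  for (tn in names(tables)) {
    for (clf in classifiers) {
      for (plan in plans) {
        key <- sprintf("%s.%s.%d", tn, clf$kind,
                       round(plan$train_fraction * 100))
        res <- train_and_evaluate(tables[[tn]], clf, plan)
        results[[key]] <- res
        rows[[key]] <- data.frame(
          table = tn, classifier = clf$kind,
          train_fraction = plan$train_fraction,
          mean_accuracy = res$mean_accuracy,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = results,
                 summary = do.call(rbind, c(rows, make.row.names = FALSE))),
            class = "mpar_grid")
}

#' @export
print.mpar_grid <- function(x, ...) {
  cat(sprintf("<mpar_grid> %d cells\n", nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Best-performing grid cell
#'
#' @param grid an `mpar_grid` from [run_grid()].
#' @return The summary row (with its key as `key`) of the cell with the
#'   highest mean accuracy.
#' @export
grid_best <- function(grid) {
  stopifnot(inherits(grid, "mpar_grid"))
  i <- which.max(grid$summary$mean_accuracy)
  out <- grid$summary[i, , drop = FALSE]
  out$key <- names(grid$results)[i]
  out
}
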