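#' Configuration for the social-distance classifier
#'
#' @param n_outer_folds stratified outer folds (default 8).
#' @param n_inner_folds inner tuning folds (default 8).
#' @param c_grid strictly increasing positive SVM cost grid; default 7
#'   logarithmically spaced points from 1e-3 to 1e3.
#' @param n_label_perms label permutations for the significance test.
#' @param seed integer seed.
#' @param multiclass_scheme `"one_vs_rest"` (default) or `"one_vs_one"`.
#' @param oversample balance training classes by oversampling (default
#'   `TRUE`; turning it off is an ablation mode).
#' @param subject_disjoint strict mode: outer folds partition subjects
#'   and a dyad is tested only in the fold containing both its members,
#'   trained on only when neither member is in the test fold.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(n_outer_folds = 8, n_inner_folds = 8,
                              c_grid = 10^seq(-3, 3), n_label_perms = 1000,
                              seed = 1L,
                              multiclass_scheme = c("one_vs_rest",
                                                    "one_vs_one"),
                              oversample = TRUE,
                              subject_disjoint = FALSE) {
  multiclass_scheme <- match.arg(multiclass_scheme)
  if (n_outer_folds < 2 || n_inner_folds < 2) {
    stop("fold counts must be >= 2", call. = FALSE)
  }
  if (any(c_grid <= 0) || is.unsorted(c_grid, strictly = TRUE)) {
    stop("c_grid must be positive and strictly increasing", call. = FALSE)
  }
  structure(list(
    n_outer_folds = as.integer(n_outer_folds),
    n_inner_folds = as.integer(n_inner_folds),
    c_grid = c_grid, n_label_perms = as.integer(n_label_perms),
    seed = as.integer(seed), multiclass_scheme = multiclass_scheme,
    oversample = oversample, subject_disjoint = subject_disjoint
  ), class = "classifier_config")
}

#' Stratified fold assignment
#'
#' Splits observations into `k` disjoint folds whose per-category counts
#' differ by at most one from an even split of that category, while
#' keeping total fold sizes as even as possible (each category's
#' remainder items go to the currently smallest folds).
#'
#' @param categories class label per observation.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(categories, k, seed = 1L) {
  cats <- unique(categories)
  counts <- table(factor(categories, levels = cats))
  if (any(counts < k)) {
    stop("every category needs at least k = ", k, " members",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- integer(length(categories))
  fold_sizes <- numeric(k)
  for (cc in cats) {
    idx <- sample(which(categories == cc))
    n_c <- length(idx)
    base <- n_c %/% k
    r <- n_c %% k
    per_fold <- rep(base, k)
    if (r > 0) {
      extra <- order(fold_sizes, seq_len(k))[seq_len(r)]
      per_fold[extra] <- per_fold[extra] + 1
    }
    assign_to <- rep(seq_len(k), per_fold)
    fold[idx] <- assign_to
    fold_sizes <- fold_sizes + per_fold
  }
  fold
}

#' Oversample a training set to balanced class counts
#'
#' Brings every class up to the size of the largest class by iteratively
#' sampling without replacement from that class's examples: full passes
#' through the class are appended until fewer than a full pass is
#' needed, then a uniform random subset completes the count. Every
#' original example is retained, and no class ever exceeds the original
#' maximum class size.
#'
#' @param features numeric matrix (rows = examples).
#' @param labels class label per row.
#' @param seed integer seed.
#' @return list with `features`, `labels`, and `index` (row indices into
#'   the input, in output order).
#' @export
oversample_training <- function(features, labels, seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  counts <- table(labels)
  if (any(counts == 0)) stop("empty class", call. = FALSE)
  m <- max(counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  index <- seq_along(labels)
  for (cc in names(counts)) {
    pool <- which(labels == cc)
    deficit <- m - length(pool)
    while (deficit >= length(pool)) {
      index <- c(index, sample(pool)) # one full pass without replacement
      deficit <- deficit - length(pool)
    }
    if (deficit > 0) {
      index <- c(index, sample(pool, deficit))
    }
  }
  list(features = features[index, , drop = FALSE],
       labels = labels[index], index = index)
}

## Linear SVM wrapper. one_vs_rest trains one binary margin per class and
## predicts by the largest decision value; one_vs_one delegates to the
## native pairwise-voting multiclass scheme.
.svm_train <- function(x, y, cost, scheme) {
  y <- factor(y)
  lev <- levels(y)
  if (scheme == "one_vs_one" || length(lev) == 2) {
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    return(list(kind = "native", fit = fit, levels = lev))
  }
  fits <- lapply(lev, function(cc) {
    yy <- factor(ifelse(y == cc, "pos", "neg"), levels = c("pos", "neg"))
    e1071::svm(x, yy, kernel = "linear", cost = cost, scale = FALSE)
  })
  list(kind = "ovr", fit = fits, levels = lev)
}

.svm_predict <- function(model, x) {
  if (model$kind == "native") {
    return(as.character(stats::predict(model$fit, x)))
  }
  dv <- vapply(model$fit, function(f) {
    pr <- stats::predict(f, x, decision.values = TRUE)
    d <- drop(attr(pr, "decision.values"))
    ## decision values are signed toward the first factor level ("pos")
    if (!startsWith(colnames(attr(pr, "decision.values"))[1], "pos")) {
      d <- -d
    }
    d
  }, numeric(nrow(x)))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = 1)
  model$levels[max.col(dv, ties.method = "first")]
}

#' Inner-loop grid search for the SVM cost parameter
#'
#' Subdivides the training data into stratified inner folds; for each
#' candidate cost, each inner training split is (optionally) oversampled
#' to balance, a linear SVM is fit, and accuracy is measured on the inner
#' validation split. Returns the cost with the highest mean validation
#' accuracy, ties broken toward the smallest cost.
#'
#' @param features training feature matrix.
#' @param labels training labels.
#' @param config a [classifier_config()].
#' @param seed integer seed (default derived from the config seed).
#' @return list with `best_c` and the `accuracy` per grid point.
#' @export
nested_grid_search <- function(features, labels, config, seed = NULL) {
  features <- as.matrix(features)
  seed <- seed %||% split_seed(config$seed, "grid")
  if (length(config$c_grid) == 1) { # degenerate grid: nothing to tune
    return(list(best_c = config$c_grid, accuracy = NA_real_))
  }
  k <- min(config$n_inner_folds, min(table(labels)))
  if (k < 2) stop("too few examples per class for inner folds",
                  call. = FALSE)
  fold <- stratified_folds(labels, k, seed)
  acc <- matrix(NA_real_, k, length(config$c_grid))
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- features[tr, , drop = FALSE]
    ytr <- labels[tr]
    if (config$oversample) {
      os <- oversample_training(xtr, ytr, split_seed(seed, paste0("os", f)))
      xtr <- os$features
      ytr <- os$labels
    }
    for (ci in seq_along(config$c_grid)) {
      fitted <- tryCatch(
        .svm_train(xtr, ytr, config$c_grid[ci],
                   config$multiclass_scheme),
        error = function(e) NULL
      )
      if (!is.null(fitted)) {
        pred <- .svm_predict(fitted, features[!tr, , drop = FALSE])
        acc[f, ci] <- mean(pred == as.character(labels[!tr]))
      }
    }
  }
  mean_acc <- colMeans(acc, na.rm = TRUE)
  if (all(is.nan(mean_acc))) stop("all inner fits failed", call. = FALSE)
  best <- which(mean_acc >= max(mean_acc, na.rm = TRUE) - 1e-12)[1]
  list(best_c = config$c_grid[best], accuracy = mean_acc)
}

#' Cross-validated social-distance prediction
#'
#' The full out-of-sample pipeline: stratified outer folds; within each
#' fold, oversampling of the training portion to balanced classes, inner
#' grid search for the SVM cost, retraining on the full (oversampled)
#' training portion, and prediction of the held-out dyads. Pooled and
#' per-fold accuracies and the row-normalized confusion matrix are
#' aggregated over all held-out predictions.
#'
#' @param dyad_vectors numeric matrix, one row per dyad (e.g. the `z_`
#'   columns of a [build_dyad_table()]).
#' @param categories distance category per dyad.
#' @param config a [classifier_config()].
#' @param dyad_ids two-column matrix/data.frame of the dyad member ids,
#'   required only for `subject_disjoint` mode.
#' @return a `classifier_result` list: `confusion` (row-normalized, rows
#'   = true category), `confusion_counts`, `overall_accuracy` (pooled
#'   over held-out predictions), `macro_accuracy` (mean of per-class
#'   recalls), `per_fold_accuracy`, `per_class_accuracy`, `fold`
#'   (assignment vector), `chosen_c`, `predictions`, `train_index` (per
#'   fold, rows used in training), `config`.
#' @export
cross_validated_predict <- function(dyad_vectors, categories, config,
                                    dyad_ids = NULL) {
  x <- as.matrix(dyad_vectors)
  if (!all(is.finite(x))) stop("non-finite features", call. = FALSE)
  y <- as.character(categories)
  stopifnot(nrow(x) == length(y))
  lev <- sort(unique(y))
  k <- config$n_outer_folds
  subj_fold <- NULL
  if (config$subject_disjoint) {
    if (is.null(dyad_ids)) {
      stop("dyad_ids required for subject_disjoint mode", call. = FALSE)
    }
    ids <- as.matrix(dyad_ids)[, 1:2, drop = FALSE]
    subjects <- sort(unique(c(ids)))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(split_seed(config$seed, "outer"))
    subj_fold <- stats::setNames(
      sample(rep_len(seq_len(k), length(subjects))), subjects
    )
    f1 <- subj_fold[ids[, 1]]
    f2 <- subj_fold[ids[, 2]]
    fold <- ifelse(f1 == f2, f1, 0L) # spanning dyads are never tested
  } else {
    fold <- stratified_folds(y, k, split_seed(config$seed, "outer"))
  }
  pred <- rep(NA_character_, length(y))
  chosen_c <- numeric(k)
  per_fold <- rep(NA_real_, k)
  train_index <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- if (config$subject_disjoint) {
      ids <- as.matrix(dyad_ids)[, 1:2, drop = FALSE]
      which(subj_fold[ids[, 1]] != f & subj_fold[ids[, 2]] != f)
    } else {
      which(fold != f)
    }
    if (length(te) == 0 || length(tr) == 0) next
    if (length(unique(y[te])) == 0) next
    xtr <- x[tr, , drop = FALSE]
    ytr <- y[tr]
    gs <- nested_grid_search(xtr, ytr, config,
                             seed = split_seed(config$seed,
                                               paste0("inner", f)))
    chosen_c[f] <- gs$best_c
    used <- tr
    if (config$oversample) {
      os <- oversample_training(xtr, ytr,
                                split_seed(config$seed, paste0("os", f)))
      xtr <- os$features
      ytr <- os$labels
      used <- tr[os$index]
    }
    train_index[[f]] <- used
    fitted <- .svm_train(xtr, ytr, gs$best_c, config$multiclass_scheme)
    pred[te] <- .svm_predict(fitted, x[te, , drop = FALSE])
    per_fold[f] <- mean(pred[te] == y[te])
  }
  scored <- !is.na(pred)
  cm <- table(factor(y[scored], levels = lev),
              factor(pred[scored], levels = lev))
  cm_norm <- sweep(unclass(cm), 1, pmax(rowSums(cm), 1), "/")
  structure(list(
    confusion = cm_norm, confusion_counts = unclass(cm),
    overall_accuracy = mean(pred[scored] == y[scored]),
    macro_accuracy = mean(diag(cm_norm)),
    per_fold_accuracy = per_fold,
    per_class_accuracy = diag(cm_norm),
    fold = fold, chosen_c = chosen_c, predictions = pred,
    train_index = train_index, config = config
  ), class = "classifier_result")
}

#' @export
print.classifier_result <- function(x, ...) {
  cat(sprintf(
    "Cross-validated social-distance classifier: accuracy %.1f%% pooled",
    100 * x$overall_accuracy
  ))
  cat(sprintf(" (%.1f%% macro; chance %.1f%%)\n",
              100 * x$macro_accuracy, 100 / nrow(x$confusion)))
  cat("Row-normalized confusion matrix (rows = true category):\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Label-permutation significance test for the classifier
#'
#' Re-runs the whole cross-validation pipeline `n_label_perms` times with
#' the labels of each training portion randomly shuffled (held-out labels
#' keep their true values for scoring), building a null distribution of
#' pooled accuracies. `p = (1 + #\{null >= observed\}) /
#' (n_label_perms + 1)`.
#'
#' @inheritParams cross_validated_predict
#' @param observed optional precomputed `classifier_result` for the
#'   unshuffled data (saves one pipeline run).
#' @return list with `p`, `observed_accuracy`, `null_accuracies`,
#'   `n_perm`.
#' @export
label_permutation_test <- function(dyad_vectors, categories, config,
                                   observed = NULL) {
  if (config$n_label_perms < 1) stop("n_perm must be >= 1", call. = FALSE)
  x <- as.matrix(dyad_vectors)
  y <- as.character(categories)
  if (is.null(observed)) {
    observed <- cross_validated_predict(x, y, config)
  }
  k <- config$n_outer_folds
  fold <- observed$fold
  null_acc <- numeric(config$n_label_perms)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(split_seed(config$seed, "labelperm"))
  for (b in seq_len(config$n_label_perms)) {
    pred <- rep(NA_character_, length(y))
    for (f in seq_len(k)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      if (length(te) == 0) next
      ytr <- sample(y[tr]) # shuffle training labels within the fold
      xtr <- x[tr, , drop = FALSE]
      gs <- tryCatch(
        nested_grid_search(xtr, ytr, config,
                           seed = split_seed(config$seed,
                                             paste0("p", b, "f", f))),
        error = function(e) NULL
      )
      cost <- if (is.null(gs)) config$c_grid[1] else gs$best_c
      if (config$oversample) {
        os <- oversample_training(xtr, ytr,
                                  split_seed(config$seed,
                                             paste0("pos", b, "f", f)))
        xtr <- os$features
        ytr <- os$labels
      }
      fitted <- .svm_train(xtr, ytr, cost, config$multiclass_scheme)
      pred[te] <- .svm_predict(fitted, x[te, , drop = FALSE])
    }
    scored <- !is.na(pred)
    null_acc[b] <- mean(pred[scored] == y[scored])
  }
  obs <- observed$overall_accuracy
  list(
    p = (1 + sum(null_acc >= obs)) / (config$n_label_perms + 1),
    observed_accuracy = obs, null_accuracies = null_acc,
    n_perm = config$n_label_perms
  )
}
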