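test_that("stratified folds balance categories and cover every dyad", {
  cats <- rep(1:4, c(63, 286, 412, 100))
  fold <- stratified_folds(cats, 8, seed = 2)
  sizes <- as.numeric(table(fold))
  expect_true(all(sizes %in% c(107, 108)))
  expect_equal(sum(sizes), 861)
  d1_per_fold <- table(fold[cats == 1])
  expect_true(all(d1_per_fold %in% c(7, 8)))
  expect_setequal(unique(fold), 1:8)

  expect_error(stratified_folds(rep(1:2, c(3, 50)), 8), "at least k")
})

test_that("oversampling balances classes without losing examples", {
  x <- matrix(seq_len(14), ncol = 2)
  labs <- rep(c("a", "b"), c(2, 5))
  os <- oversample_training(x, labs, seed = 1)
  expect_equal(as.numeric(table(os$labels)), c(5, 5))
  ## all originals retained
  expect_true(all(seq_along(labs) %in% os$index))
  ## the two minority examples appear 2 or 3 times each (full pass + 1)
  counts <- table(os$index[os$labels == "a"])
  expect_true(all(counts %in% 2:3))
  expect_equal(sum(counts), 5)

  ## already balanced: identity
  os2 <- oversample_training(x[1:6, ], rep(c("a", "b"), each = 3),
                             seed = 1)
  expect_equal(os2$index, 1:6)

  ## determinism
  os3 <- oversample_training(x, labs, seed = 1)
  expect_identical(os$index, os3$index)
})

test_that("grid search prefers the smallest cost on ties", {
  set.seed(3)
  x <- rbind(matrix(rnorm(40, -10), ncol = 2),
             matrix(rnorm(40, 10), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  cfg <- classifier_config(n_outer_folds = 2, n_inner_folds = 4,
                           c_grid = c(0.01, 1, 100), seed = 1)
  gs <- nested_grid_search(x, y, cfg)
  expect_equal(gs$best_c, 0.01) # wide margin: every C is perfect
  expect_true(all(gs$accuracy == 1))

  cfg1 <- classifier_config(n_outer_folds = 2, n_inner_folds = 4,
                            c_grid = 0.5, seed = 1)
  expect_equal(nested_grid_search(x, y, cfg1)$best_c, 0.5)
})

test_that("invalid classifier configurations are rejected", {
  expect_error(classifier_config(c_grid = c(1, 1)), "increasing")
  expect_error(classifier_config(c_grid = c(-1, 1)), "positive")
  expect_error(classifier_config(n_outer_folds = 1), "fold")
})

test_that("perfect features yield perfect cross-validated predictions", {
  set.seed(4)
  cats <- sample(rep(1:4, each = 30))
  x <- model.matrix(~ factor(cats) - 1) + matrix(rnorm(480, sd = 0.01),
                                                 ncol = 4)
  cfg <- classifier_config(n_outer_folds = 4, n_inner_folds = 3,
                           c_grid = c(0.1, 10), n_label_perms = 19,
                           seed = 5)
  res <- cross_validated_predict(x, cats, cfg)
  expect_equal(res$overall_accuracy, 1)
  expect_equal(unname(res$confusion), diag(4), ignore_attr = TRUE)
  expect_true(all(res$per_fold_accuracy == 1))
  expect_true(all(abs(rowSums(res$confusion) - 1) < 1e-9))

  lp <- label_permutation_test(x, cats, cfg, observed = res)
  expect_equal(lp$p, 1 / 20)
})

test_that("no held-out dyad influences training in its own fold", {
  set.seed(6)
  cats <- sample(rep(1:3, each = 20))
  x <- matrix(rnorm(60 * 5), ncol = 5)
  cfg <- classifier_config(n_outer_folds = 3, n_inner_folds = 2,
                           c_grid = c(0.1, 10), seed = 7)
  res <- cross_validated_predict(x, cats, cfg)
  for (f in 1:3) {
    test_idx <- which(res$fold == f)
    expect_length(intersect(res$train_index[[f]], test_idx), 0)
  }
  expect_true(all(!is.na(res$predictions)))

  ## the whole pipeline is a pure function of (features, labels, config)
  res2 <- cross_validated_predict(x, cats, cfg)
  expect_identical(res$predictions, res2$predictions)
  expect_identical(res$chosen_c, res2$chosen_c)
})

test_that("ablation without oversampling still runs", {
  set.seed(8)
  cats <- rep(1:3, c(10, 25, 25))
  x <- matrix(rnorm(60 * 4), ncol = 4) + outer(cats, rep(0.5, 4))
  cfg <- classifier_config(n_outer_folds = 3, n_inner_folds = 2,
                           c_grid = 1, oversample = FALSE, seed = 9)
  res <- cross_validated_predict(x, cats, cfg)
  expect_true(is.finite(res$overall_accuracy))
  ## training never inflates a class beyond its original maximum
  cfg_os <- classifier_config(n_outer_folds = 3, n_inner_folds = 2,
                              c_grid = 1, seed = 9)
  res_os <- cross_validated_predict(x, cats, cfg_os)
  for (f in 1:3) {
    tr_labs <- cats[res_os$train_index[[f]]]
    orig <- table(cats[which(res_os$fold != f)])
    expect_true(all(table(tr_labs) <= max(orig)))
  }
})

test_that("subject-disjoint mode never trains on a test subject", {
  st <- small_study(seed = 51, n_subjects = 16, n_cohort = 50,
                    n_rois = 6, n_timepoints = 60)
  tab <- st$dyad_table
  feats <- as.matrix(tab[, grep("^z_", names(tab))])
  cfg <- classifier_config(n_outer_folds = 2, n_inner_folds = 2,
                           c_grid = 1, subject_disjoint = TRUE, seed = 3)
  res <- tryCatch(
    cross_validated_predict(feats, tab$distance, cfg,
                            dyad_ids = tab[, c("id_i", "id_j")]),
    error = function(e) NULL
  )
  if (!is.null(res)) {
    for (f in 1:2) {
      te <- which(res$fold == f)
      if (length(te) == 0) next
      test_subjects <- unique(unlist(tab[te, c("id_i", "id_j")]))
      tr <- res$train_index[[f]]
      train_subjects <- unique(unlist(tab[tr, c("id_i", "id_j")]))
      expect_length(intersect(test_subjects, train_subjects), 0)
    }
  }
  expect_error(
    cross_validated_predict(feats, tab$distance, cfg),
    "dyad_ids"
  )
})
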