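# Balanced accuracy, grids, nested CV, model comparison, importance.

test_that("balanced accuracy equals mean per-class recall", {
  expect_equal(balanced_accuracy(diag(c(10, 10, 10))), 1.0)
  # all predictions collapse to one class on balanced truth
  collapsed <- matrix(c(10, 0, 0, 10, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  expect_equal(balanced_accuracy(collapsed), 1 / 3)
  # hand-derived: recalls 0.8, 0.8, 0.8
  cm <- matrix(c(8, 2, 0, 1, 8, 1, 0, 2, 8), 3, 3, byrow = TRUE)
  expect_equal(balanced_accuracy(cm), 0.8)
  # brute-force oracle on random confusion matrices
  set.seed(5)
  for (i in 1:1000) {
    m <- matrix(rpois(9, 5) + diag(3), 3, 3)
    expect_equal(balanced_accuracy(m), oracle_ba(m), tolerance = 1e-12)
  }
  bad <- matrix(c(0, 0, 0, 1, 5, 1, 0, 2, 8), 3, 3, byrow = TRUE,
                dimnames = list(c("baseline", "full", "micturition"), NULL))
  expect_error(balanced_accuracy(bad), "baseline")
})

test_that("model grids carry the declared search spaces and reject unknowns", {
  rf <- model_grid("rf")
  expect_identical(rf$grid$num_trees, c(50, 100, 200, 300))
  expect_identical(rf$grid$max_depth, c(5, 10, 20, 30))
  svm <- model_grid("svm")
  expect_identical(svm$grid$kernel, c("sigmoid", "rbf"))
  expect_identical(svm$grid$cost, c(1e-3, 1e-2, 1e-1, 1))
  expect_identical(model_grid("knn")$grid$k, c(3, 5, 7, 9, 11))
  mlp <- model_grid("mlp")
  expect_length(mlp$grid$hidden, 5L)
  expect_identical(mlp$grid$hidden[[3]], c(128, 256, 512, 128))
  expect_identical(mlp$grid$learning_rate, 1e-3)
  expect_error(model_grid("rf", trees = 10), "unknown hyperparameter")
  expect_error(model_grid("lda"))
  # grid points enumerate all combinations
  expect_length(engdecode:::grid_points(rf), 16L)
  expect_length(engdecode:::grid_points(svm), 8L)
})

tab <- small_table()

test_that("nested CV selects from the grid, deterministically", {
  grid <- model_grid("rf", num_trees = c(50, 100), max_depth = c(10, 20))
  cv <- nested_cv(tab, grid, n_outer = 5, n_inner = 2, seed = 17)
  for (p in cv$fold_params) {
    expect_true(p$num_trees %in% c(50, 100))
    expect_true(p$max_depth %in% c(10, 20))
  }
  expect_length(cv$fold_ba, 5L)
  expect_true(all(cv$fold_ba >= 0 & cv$fold_ba <= 1))
  # per-fold confusion matrix rows sum to that fold's test windows per class
  for (k in 1:5) {
    expect_identical(as.integer(rowSums(cv$fold_cm[[k]])),
                     as.integer(table(tab$labels[cv$fold == k])))
  }
  # determinism
  cv2 <- nested_cv(tab, grid, n_outer = 5, n_inner = 2, seed = 17)
  expect_identical(cv$fold_ba, cv2$fold_ba)
  expect_identical(cv$fold_params, cv2$fold_params)
  expect_identical(cv$importance$per_column, cv2$importance$per_column)
  # refuses standardized or shuffled input
  expect_error(nested_cv(standardize(tab), grid), "unstandardized")
  expect_error(nested_cv(shuffle_rows(tab, 1), grid), "timeline order")
})

test_that("outer folds are contiguous per class and shared across models", {
  grid <- model_grid("rf", num_trees = 50, max_depth = 10)
  cv <- nested_cv(tab, grid, n_outer = 5, n_inner = 2, seed = 17)
  for (cl in levels(tab$labels)) {
    f <- cv$fold[tab$labels == cl]
    expect_true(all(diff(f) >= 0)) # contiguous-in-time blocks
    expect_identical(sort(unique(f)), 1:5)
  }
  cmp <- compare_models(
    tab,
    grids = list(model_grid("rf", num_trees = 50, max_depth = 10),
                 model_grid("knn", k = 5)),
    n_outer = 5, n_inner = 2, seed = 17
  )
  expect_identical(cmp$reports$rf$fold, cmp$reports$knn$fold)
  expect_identical(cmp$ranking$rank, 1:2)
})

test_that("easy synthetic data is decoded near-perfectly by all models", {
  cmp <- compare_models(
    tab,
    grids = list(model_grid("rf", num_trees = 100, max_depth = 20),
                 model_grid("svm", kernel = "rbf", cost = 1),
                 model_grid("knn", k = 5),
                 model_grid("mlp", hidden = list(c(128, 128, 128, 128)))),
    n_outer = 5, n_inner = 2, seed = 3
  )
  for (r in cmp$reports) expect_gte(r$mean_ba, 0.9)
})

test_that("mean BA never decreases with generator class separation", {
  # three separability levels, fixed seeds: identical states, mild, strong
  levels_rates <- list(
    c(baseline = 40, full = 40, micturition = 40),
    c(baseline = 30, full = 40, micturition = 55),
    c(baseline = 10, full = 40, micturition = 90)
  )
  levels_amps <- list(
    c(baseline = 10, full = 10, micturition = 10),
    c(baseline = 9, full = 10, micturition = 11),
    c(baseline = 8, full = 10, micturition = 12)
  )
  grid <- model_grid("rf", num_trees = 100, max_depth = 20)
  bas <- vapply(1:3, function(i) {
    s <- small_session(seed = 500L, segment_s = 6, n_channels = 4L,
                       n_dead = 0L, rates = levels_rates[[i]],
                       amps = levels_amps[[i]])
    t <- small_table(s)
    nested_cv(t, grid, n_outer = 4, n_inner = 2, seed = 11)$mean_ba
  }, numeric(1))
  expect_true(all(diff(bas) >= 0))
  # chance at the degenerate level, near-perfect at the strong level
  expect_lt(bas[1], 0.55)
  expect_gt(bas[3], 0.9)
})

test_that("Gini importance normalizes, aggregates, and flags dead channels", {
  cv <- nested_cv(tab, model_grid("rf", num_trees = 100, max_depth = 20),
                  n_outer = 5, n_inner = 2, seed = 2)
  imp <- gini_importance(cv)
  expect_equal(sum(imp$per_column), 1, tolerance = 1e-9)
  # aggregates recompute from per-column values
  expect_equal(unname(imp$per_channel["ch01"]),
               sum(imp$per_column[grepl("^ch01_", names(imp$per_column))]))
  expect_equal(unname(imp$per_feature["VAR"]),
               mean(imp$per_column[grepl("_VAR$", names(imp$per_column))]))
  # dead channel (noise only) weighs less than the median functional channel
  status <- small_session()$channel_status
  dead <- which(status == "dead")
  expect_lt(max(imp$per_channel[dead]),
            stats::median(imp$per_channel[status == "functional"]))
  # non-RF fits are unsupported
  kcv <- nested_cv(tab, model_grid("knn", k = 5), n_outer = 5, n_inner = 2,
                   seed = 2)
  expect_error(gini_importance(kcv), "random-forest")
})

test_that("variance-only class contrast ranks VAR at the top", {
  vt <- variance_only_table()
  std <- standardize(vt)
  sh <- shuffle_rows(std, seed = 4)
  fit <- engdecode:::fit_model("rf", list(num_trees = 200, max_depth = 20),
                               sh$x, sh$labels, seed = 8, importance = TRUE)
  imp <- gini_importance(fit, vt$column_names)
  top2 <- names(sort(imp$per_feature, decreasing = TRUE))[1:2]
  expect_true("VAR" %in% top2)
  expect_true(all(top2 %in% c("VAR", "POW")))
})
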