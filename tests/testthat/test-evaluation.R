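test_that("jackknife folds are n singletons; stratified folds balance every class", {
  s <- xylanase_strains()
  jk <- make_folds(s$real_class, validation_scheme("jackknife"))
  expect_equal(sort(jk), 1:41)

  sch <- validation_scheme("stratified_kfold", k = 10, seed = 4)
  folds <- make_folds(s$real_class, sch)
  expect_length(folds, 41)
  for (cl in levels(s$real_class)) {
    per_fold <- tabulate(folds[s$real_class == cl], nbins = 10)
    n_c <- sum(s$real_class == cl)
    expect_true(all(per_fold %in% c(floor(n_c / 10), ceiling(n_c / 10))), label = cl)
  }
  # seeded reproducibility
  expect_identical(folds, make_folds(s$real_class, sch))
  expect_error(make_folds(rep("a", 5), validation_scheme(k = 10)),
               class = "xyl_param_error")
})

test_that("the stratified balance invariant holds across many seeds on the study classes", {
  s <- xylanase_strains()
  counts <- as.vector(table(s$real_class))
  for (seed in 1:200) {
    folds <- make_folds(s$real_class, validation_scheme("stratified_kfold", k = 10, seed = seed))
    for (i in seq_along(levels(s$real_class))) {
      per_fold <- tabulate(folds[as.integer(s$real_class) == i], nbins = 10)
      expect_true(all(per_fold %in% c(floor(counts[i] / 10), ceiling(counts[i] / 10))))
    }
  }
})

test_that("classification metrics match hand-computed confusion-table values", {
  perfect <- classification_metrics(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(unlist(perfect[c("ca", "f1", "precision", "recall")]),
               c(ca = 1, f1 = 1, precision = 1, recall = 1))

  m <- classification_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
  expect_equal(m$ca, 0.75)
  # per class: A p=1 r=.5 f1=2/3; B p=2/3 r=1 f1=.8; equal support weights
  expect_equal(m$precision, (1 + 2 / 3) / 2)
  expect_equal(m$recall, 0.75)
  expect_equal(m$f1, (2 / 3 + 0.8) / 2)

  # class-independent scores give a chance-level AUC
  truth <- rep(c("L", "M", "H"), each = 4)
  sc <- matrix(1 / 3, 12, 3, dimnames = list(NULL, c("L", "M", "H")))
  flat <- classification_metrics(truth, truth, sc)
  expect_equal(flat$auc, 0.5)

  expect_error(
    classification_metrics(truth, truth, sc[, 1:2]),
    class = "xyl_score_schema_error"
  )
})

test_that("regression metrics match hand arithmetic and internal identities", {
  exact <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(exact), c(mse = 0, rmse = 0, mae = 0, r2 = 1))

  m <- regression_metrics(c(0, 0, 3, 3), c(1, 1, 2, 2))
  expect_equal(unlist(m), c(mse = 1, rmse = 1, mae = 1, r2 = 1 - 4 / 9))

  withr::with_seed(3, {
    for (i in 1:10) {
      t <- rnorm(15)
      p <- rnorm(15)
      r <- regression_metrics(t, p)
      expect_equal(r$rmse^2, r$mse, tolerance = 1e-12)
    }
  })
  expect_error(regression_metrics(rep(2, 5), rnorm(5)),
               class = "xyl_degenerate_target_error")
})

test_that("cross-validation pools exactly one out-of-fold prediction per sample", {
  sim <- simulate_dataset(sim_config(n_sequences = 30, seed = 2))
  for (kind in c("stratified_kfold", "jackknife")) {
    cv <- cross_validate(sim$features, sim$strains$act_pH4_T60,
                         model_preset("knn_regressor"),
                         validation_scheme(kind, k = 5, seed = 1))
    expect_equal(nrow(tidy(cv)), 30)
    expect_true(all(!is.na(tidy(cv)$pred)))
    expect_equal(glance(cv)$n, 30)
  }
})

test_that("jackknife KNN results are permutation-invariant and run-to-run identical", {
  sim <- simulate_dataset(sim_config(n_sequences = 25, seed = 6))
  feats <- sim$features
  y <- sim$strains$act_pH4_T26
  jk <- validation_scheme("jackknife")
  cfg <- model_preset("knn_regressor")
  a <- glance(cross_validate(feats, y, cfg, jk))
  b <- glance(cross_validate(feats, y, cfg, jk))
  expect_identical(a, b)

  withr::with_seed(10, perm <- sample(25))
  c_ <- glance(cross_validate(feats[perm, ], y[perm], cfg, jk))
  expect_equal(c_[c("mse", "rmse", "mae", "r2")], a[c("mse", "rmse", "mae", "r2")],
               tolerance = 1e-12)

  # classification path too
  yc <- sim$strains$real_class
  ca1 <- glance(cross_validate(feats, yc, model_preset("knn_classifier"), jk))
  ca2 <- glance(cross_validate(feats[perm, ], yc[perm], model_preset("knn_classifier"), jk))
  expect_equal(ca1$ca, ca2$ca)
})

test_that("a leave-one-out mean predictor never beats the pooled-mean baseline", {
  # k = n_train makes KNN predict the training mean: LOO mean prediction
  # always has SSE >= SStot, so R^2 <= 0
  withr::with_seed(14, {
    for (i in 1:5) {
      n <- 20
      X <- tibble::as_tibble(matrix(rnorm(n * 3), n, 3,
                                    dimnames = list(NULL, paste0("f", 1:3))))
      y <- rnorm(n)
      cv <- cross_validate(X, y, model_preset("knn_regressor", k = n - 1),
                           validation_scheme("jackknife"))
      expect_lte(glance(cv)$r2, 0)
    }
  })
})

test_that("the results grid covers all models, schemes and flags exact cells only for jackknife KNN", {
  sim <- simulate_dataset(sim_config(n_sequences = 24, seed = 5))
  strains <- sim$strains
  grid <- reproduce_tables(strains, sim$features, seed = 1, conditions = "pH4_T26")
  expect_equal(sort(unique(grid$model)),
               sort(c("rf_classifier", "svm_classifier", "knn_classifier", "naive_bayes",
                      "svm_regressor", "knn_regressor", "adaboost_regressor", "rf_regressor")))
  expect_setequal(unique(grid$scheme), c("10-fold", "jackknife"))
  expect_setequal(grid$metric[grid$task == "regression"], c("mse", "rmse", "mae", "r2"))
  expect_setequal(grid$metric[grid$task == "classification"],
                  c("auc", "ca", "f1", "precision", "recall"))
  exact_cells <- unique(grid[grid$exact, c("model", "scheme")])
  expect_equal(nrow(exact_cells), 2)
  expect_setequal(exact_cells$model, c("knn_classifier", "knn_regressor"))
  expect_equal(unique(exact_cells$scheme), "jackknife")

  expect_error(reproduce_tables(strains, sim$features[-1, ], seed = 1),
               class = "xyl_alignment_error")
})

test_that("tidy, glance and autoplot expose the evaluation report", {
  sim <- simulate_dataset(sim_config(n_sequences = 20, seed = 9))
  cv <- cross_validate(sim$features, sim$strains$real_class,
                       model_preset("knn_classifier"), validation_scheme("jackknife"))
  td <- tidy(cv)
  expect_true(all(c("id", "fold", "truth", "pred", ".score_L") %in% names(td)))
  gl <- glance(cv)
  expect_true(all(c("model", "scheme", "auc", "ca") %in% names(gl)))
  expect_s3_class(autoplot(cv), "ggplot")

  cvr <- cross_validate(sim$features, sim$strains$act_pH6_T26,
                        model_preset("knn_regressor"), validation_scheme("jackknife"))
  expect_s3_class(autoplot(cvr), "ggplot")
})
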