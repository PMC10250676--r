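test_that("stratified split keeps class proportions within one row", {
  tbl <- toy_feature_table(500, shift = 1, seed = 1)
  parts <- split_train_test(tbl, train_fraction = 0.8, seed = 5)
  expect_identical(nrow(parts$train), 800L)
  expect_identical(nrow(parts$test), 200L)
  expect_equal(as.vector(table(parts$train$label)), c(400L, 400L))
  expect_equal(as.vector(table(parts$test$label)), c(100L, 100L))
  expect_identical(nrow(dplyr::intersect(parts$train, parts$test)), 0L)

  again <- split_train_test(tbl, train_fraction = 0.8, seed = 5)
  expect_identical(parts$train, again$train)

  four <- toy_feature_table(2, shift = 0, seed = 2)
  half <- split_train_test(four, train_fraction = 0.5, seed = 1)
  expect_equal(as.vector(table(half$train$label)), c(1L, 1L))
  expect_equal(as.vector(table(half$test$label)), c(1L, 1L))

  tiny <- toy_feature_table(1, shift = 0, seed = 2)
  expect_error(split_train_test(tiny), class = "stromatex_error_validation")
  expect_error(split_train_test(tbl, train_fraction = 1), class = "stromatex_error_validation")
})

test_that("both classifiers separate well-separated clouds perfectly", {
  tbl <- toy_feature_table(50, shift = 10, seed = 4)
  parts <- split_train_test(tbl, seed = 4)
  for (mo in c("rf", "svm")) {
    fit <- fit_texture_classifier(parts$train, model = mo, seed = 4)
    pred <- predict(fit, parts$test, type = "class")
    truth <- ifelse(parts$test$label == "g4", "pos", "neg")
    expect_equal(mean(as.character(pred) == truth), 1)
    expect_equal(cross_val_accuracy(parts$train, model = mo, seed = 4), 1)
  }
})

test_that("training and prediction are pure functions of data and seed", {
  tbl <- toy_feature_table(40, shift = 1, seed = 6)
  for (mo in c("rf", "svm")) {
    f1 <- fit_texture_classifier(tbl, model = mo, seed = 9)
    f2 <- fit_texture_classifier(tbl, model = mo, seed = 9)
    expect_identical(predict(f1, tbl, type = "score"),
                     predict(f2, tbl, type = "score"))
  }
  cv1 <- cross_val_predict(tbl, model = "rf", seed = 9)
  cv2 <- cross_val_predict(tbl, model = "rf", seed = 9)
  expect_identical(cv1, cv2)
})

test_that("single-class training data is rejected", {
  tbl <- toy_feature_table(10, shift = 0, seed = 1)
  one <- tbl[tbl$label == "native", ]
  expect_error(fit_texture_classifier(one, model = "rf"),
               class = "stromatex_error_validation")
  expect_error(fit_texture_classifier(one, model = "svm"),
               class = "stromatex_error_validation")
})

test_that("rescaling one feature leaves SVM predictions unchanged", {
  tbl <- toy_feature_table(40, shift = 2, seed = 10)
  fit1 <- fit_texture_classifier(tbl, model = "svm", seed = 2)
  scaled <- tbl
  scaled$asm <- scaled$asm * 1000
  fit2 <- fit_texture_classifier(scaled, model = "svm", seed = 2)
  p1 <- predict(fit1, tbl, type = "class")
  p2 <- predict(fit2, scaled, type = "class")
  expect_identical(as.character(p1), as.character(p2))
})

test_that("uninformative features yield chance-level cross-validated accuracy", {
  tbl <- toy_feature_table(200, shift = 0, seed = 14)  # n = 400, pure noise
  acc <- cross_val_accuracy(tbl, model = "svm", seed = 14)
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})

test_that("ROC handles perfect, tied and reversed rankings", {
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  perfect <- roc_curve_auc(as.numeric(labels), labels)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(perfect$points$tpr[1], 0)
  expect_equal(utils::tail(perfect$points$fpr, 1), 1)
  expect_equal(utils::tail(perfect$points$tpr, 1), 1)

  set.seed(20)
  scores <- sample(1:6, 40, replace = TRUE)  # many ties
  labs <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(.5, .5))
  r <- roc_curve_auc(scores, labs)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  # antisymmetry under score negation
  expect_equal(r$auc + roc_curve_auc(-scores, labs)$auc, 1, tolerance = 1e-12)
  expect_error(roc_curve_auc(scores, rep(TRUE, 40)), class = "stromatex_error_validation")
})

test_that("trapezoidal AUC equals the Mann-Whitney oracle and pROC", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(20:200, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    r <- roc_curve_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-10)
    # AUC equals the trapezoidal area of the returned polygon
    area <- sum(diff(r$points$fpr) *
                  (utils::head(r$points$tpr, -1) + utils::tail(r$points$tpr, -1)) / 2)
    expect_equal(r$auc, area, tolerance = 1e-9)
  }
  skip_if_not_installed("pROC")
  set.seed(99)
  scores <- rnorm(150)
  labels <- sample(c(TRUE, FALSE), 150, replace = TRUE)
  ours <- roc_curve_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("cross-validation predicts every row exactly once, stratified", {
  tbl <- toy_feature_table(25, shift = 1, seed = 30)
  cv <- cross_val_predict(tbl, model = "rf", folds = 5, seed = 30)
  expect_identical(cv$row, seq_len(50L))
  expect_identical(sort(unique(cv$fold)), 1:5)
  # stratification: each fold holds 5 rows of each class
  per_fold <- table(cv$fold, cv$truth)
  expect_true(all(per_fold == 5L))
  expect_error(cross_val_predict(tbl, model = "rf", folds = 30),
               class = "stromatex_error_validation")
})

test_that("evaluate_classifiers reports split, CV and ROC metrics coherently", {
  tbl <- toy_feature_table(60, shift = 4, seed = 40)
  rep <- evaluate_classifiers(tbl, seed = 40)
  gl <- generics::glance(rep)
  expect_identical(gl$model, c("rf", "svm"))
  expect_true(all(gl$test_accuracy > 0.9))
  expect_true(all(gl$auc > 0.9))
  expect_identical(rep$n_train + rep$n_test, 120L)
  expect_identical(rep$positive, "g4")
  td <- generics::tidy(rep)
  expect_true(all(c("model", "fpr", "tpr") %in% names(td)))
  # roc endpoints for each model
  for (m in rep$models) {
    expect_equal(m$roc$fpr[1], 0)
    expect_equal(utils::tail(m$roc$tpr, 1), 1)
  }
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
})

test_that("no leakage: test-time standardization reuses training statistics", {
  tbl <- toy_feature_table(40, shift = 2, seed = 50)
  parts <- split_train_test(tbl, seed = 50)
  fit <- fit_texture_classifier(parts$train, model = "svm", seed = 50)
  # scores on test rows must be identical whether or not other test rows are
  # present in the prediction batch (statistics must come from training only)
  s_all <- predict(fit, parts$test, type = "score")
  s_one <- vapply(seq_len(nrow(parts$test)), function(i) {
    predict(fit, parts$test[i, , drop = FALSE], type = "score")
  }, numeric(1))
  expect_equal(s_all, s_one, tolerance = 1e-10)
})
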