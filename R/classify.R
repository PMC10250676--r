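#' Stratified train/test split of a feature table
#'
#' Splits rows into training and test parts, stratified by class so that each
#' part's class proportions match the overall proportions to within one row,
#' using a seeded generator. Parts are disjoint and exhaustive.
#'
#' @param df Feature table with a class column.
#' @param train_fraction Fraction of rows used for training (default 0.8).
#' @param stratified Stratify by class? Default `TRUE`.
#' @param seed Integer seed.
#' @param group Name of the class column (default `"label"`).
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(df, train_fraction = 0.8, stratified = TRUE,
                             seed = 1L, group = "label") {
  if (!is.data.frame(df) || !group %in% names(df)) {
    abort_validation(sprintf("`df` must be a data frame with a '%s' column.", group))
  }
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    abort_validation("`train_fraction` must lie strictly between 0 and 1.")
  }
  g <- factor(df[[group]])
  if (any(table(g) < 2L)) {
    abort_validation("Every class needs at least 2 rows to be split.")
  }
  train_idx <- with_seed(derive_seed(seed, 211L), {
    if (stratified) {
      unlist(lapply(levels(g), function(cl) {
        idx <- which(g == cl)
        n_tr <- round(train_fraction * length(idx))
        n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
        sample(idx, n_tr)
      }), use.names = FALSE)
    } else {
      n_tr <- round(train_fraction * nrow(df))
      n_tr <- min(max(n_tr, 1L), nrow(df) - 1L)
      sample(nrow(df), n_tr)
    }
  })
  train_idx <- sort(train_idx)
  list(
    train = df[train_idx, , drop = FALSE],
    test = df[-train_idx, , drop = FALSE]
  )
}

default_hyperparams <- function(model, n_features) {
  switch(model,
    rf = list(ntree = 100L, mtry = ceiling(sqrt(n_features))),
    svm = list(kernel = "radial", cost = 1, gamma = 1 / n_features, scale = TRUE)
  )
}

classifier_matrix <- function(df, feature_names) {
  missing <- setdiff(feature_names, names(df))
  if (length(missing) > 0L) {
    abort_validation(sprintf(
      "Feature column(s) missing from table: %s.", paste(missing, collapse = ", ")
    ))
  }
  x <- as.matrix(df[, feature_names, drop = FALSE])
  if (!all(is.finite(x))) abort_validation("Feature table contains non-finite values.")
  x
}

binary_outcome <- function(labels, positive) {
  labs <- as.character(labels)
  u <- unique(labs)
  if (length(u) < 2L) abort_validation("Training data must contain both classes.")
  if (length(u) > 2L) {
    abort_validation("Classification expects exactly two classes; subset the table first.")
  }
  if (is.null(positive)) {
    positive <- if ("native" %in% u) setdiff(u, "native") else sort(u)[2]
  }
  if (!positive %in% u) {
    abort_validation(sprintf("`positive` class '%s' not present in the labels.", positive))
  }
  factor(ifelse(labs == positive, "pos", "neg"), levels = c("neg", "pos"))
}

#' Fit a texture classifier (random forest or RBF-kernel SVM)
#'
#' Random forest: an ensemble of classification trees grown on bootstrap
#' samples with random feature subsets at each split (defaults: 100 trees,
#' `ceiling(sqrt(p))` candidate features per split, no depth cap); the ROC
#' score of a ROI is the fraction of trees voting for the positive class.
#' SVM: a margin-maximizing classifier with a radial basis kernel (defaults:
#' `cost = 1`, `gamma = 1/p`); features are standardized to zero mean and
#' unit variance using training-set statistics only, and the same transform
#' is applied at prediction time; the ROC score is the signed decision value.
#' Both fits are pure functions of (data, hyperparameters, seed).
#'
#' @param train Training feature table with a `label` column.
#' @param model `"rf"` or `"svm"`.
#' @param positive Label value treated as the positive (decellularized)
#'   class; defaults to the non-`"native"` label of a two-class table.
#' @param hyperparams Named list overriding the defaults above.
#' @param seed Integer seed.
#' @param feature_names Feature columns (default the eight texture features).
#' @return An object of class `texture_model`.
#' @export
fit_texture_classifier <- function(train, model = c("rf", "svm"),
                                   positive = NULL, hyperparams = list(),
                                   seed = 1L,
                                   feature_names = texture_feature_names()) {
  model <- match.arg(model)
  x <- classifier_matrix(train, feature_names)
  y <- binary_outcome(train$label, positive)
  if (nlevels(droplevels(y)) < 2L) {
    abort_validation("Training data must contain both classes.")
  }
  hp <- utils::modifyList(default_hyperparams(model, ncol(x)), hyperparams)
  fit <- with_seed(derive_seed(seed, 307L), {
    if (model == "rf") {
      randomForest::randomForest(
        x = x, y = y, ntree = hp$ntree, mtry = hp$mtry
      )
    } else {
      e1071::svm(
        x = x, y = y, kernel = hp$kernel, cost = hp$cost, gamma = hp$gamma,
        scale = hp$scale
      )
    }
  })
  positive_label <- {
    labs <- as.character(train$label)
    u <- unique(labs)
    if (is.null(positive)) {
      if ("native" %in% u) setdiff(u, "native") else sort(u)[2]
    } else {
      positive
    }
  }
  structure(
    list(model_type = model, fit = fit, feature_names = feature_names,
         positive = positive_label, hyperparams = hp, seed = as.integer(seed)),
    class = "texture_model"
  )
}

#' @export
print.texture_model <- function(x, ...) {
  cat(sprintf(
    "<texture_model> %s on %d features, positive class '%s', seed %d\n",
    toupper(x$model_type), length(x$feature_names), x$positive, x$seed
  ))
  invisible(x)
}

#' Predict from a fitted texture classifier
#'
#' @param object A `texture_model`.
#' @param newdata Feature table with the model's feature columns.
#' @param type `"class"` for predicted labels (`"pos"`/`"neg"`) or `"score"`
#'   for the ranking score used for ROC analysis (vote fraction for the
#'   random forest, signed decision value for the SVM; higher favors the
#'   positive class).
#' @param ... Unused.
#' @return A factor (`type = "class"`) or numeric vector (`type = "score"`).
#' @export
predict.texture_model <- function(object, newdata,
                                  type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- classifier_matrix(newdata, object$feature_names)
  if (object$model_type == "rf") {
    if (type == "class") {
      return(stats::predict(object$fit, x))
    }
    prob <- stats::predict(object$fit, x, type = "prob")
    return(unname(prob[, "pos"]))
  }
  if (type == "class") {
    return(stats::predict(object$fit, x))
  }
  pred <- stats::predict(object$fit, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  s <- as.numeric(dv[, 1])
  # e1071 reports the decision value for "<first>/<second>"; flip so that
  # larger scores always favor the positive class
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (first != "pos") s <- -s
  s
}

#' Empirical ROC curve and area under it
#'
#' Sweeps the decision threshold over the unique score values (ties grouped
#' into single steps), returning the ROC polygon from (0, 0) to (1, 1) and
#' its trapezoidal area. The trapezoidal AUC equals the normalized
#' Mann-Whitney U statistic with ties counted 1/2.
#'
#' @param scores Numeric ranking scores (higher favors the positive class).
#' @param labels Positive-class indicator: logical, 0/1, or a factor whose
#'   second level is positive.
#' @return An object of class `roc_result`: a list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2]
  if (is.numeric(labels)) labels <- labels == 1
  if (!is.logical(labels) || length(labels) != length(scores)) {
    abort_validation("`labels` must be a binary vector matching `scores` in length.")
  }
  if (anyNA(scores) || anyNA(labels)) abort_validation("Scores and labels must not be missing.")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort_validation("ROC analysis needs both classes present.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)  # index of the last element of each tie group
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  points <- tibble::tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  structure(
    list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d pos / %d neg, %d points)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Out-of-fold predictions from stratified k-fold cross-validation
#'
#' Assigns rows to `folds` stratified folds with a seeded generator, then
#' predicts each row exactly once with a model trained on the other folds.
#'
#' @param df Feature table with a `label` column.
#' @param model,positive,hyperparams,seed,feature_names As in
#'   [fit_texture_classifier()]; `seed` also fixes the fold assignment.
#' @param folds Number of folds (default 5); each class must have at least
#'   `folds` rows.
#' @return A tibble with one row per input row: `fold`, `truth`
#'   (`"pos"`/`"neg"`), `pred`, `score`.
#' @export
cross_val_predict <- function(df, model = c("rf", "svm"), folds = 5L,
                              positive = NULL, hyperparams = list(),
                              seed = 1L,
                              feature_names = texture_feature_names()) {
  model <- match.arg(model)
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2L) abort_validation("`folds` must be >= 2.")
  y <- binary_outcome(df$label, positive)
  if (any(table(y) < folds)) {
    abort_validation(sprintf(
      "Each class needs at least %d rows for %d-fold stratified CV.", folds, folds
    ))
  }
  fold_id <- integer(nrow(df))
  with_seed(derive_seed(seed, 401L), {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  out <- vector("list", folds)
  for (k in seq_len(folds)) {
    hold <- fold_id == k
    fit <- fit_texture_classifier(
      df[!hold, , drop = FALSE], model = model, positive = positive,
      hyperparams = hyperparams, seed = derive_seed(seed, 500L + k),
      feature_names = feature_names
    )
    out[[k]] <- tibble::tibble(
      row = which(hold),
      fold = k,
      truth = as.character(y[hold]),
      pred = as.character(predict(fit, df[hold, , drop = FALSE], type = "class")),
      score = predict(fit, df[hold, , drop = FALSE], type = "score")
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$row)
}

#' Pooled k-fold cross-validated accuracy
#'
#' @inheritParams cross_val_predict
#' @return The pooled fraction of correctly classified rows.
#' @export
cross_val_accuracy <- function(df, model = c("rf", "svm"), folds = 5L,
                               positive = NULL, hyperparams = list(),
                               seed = 1L,
                               feature_names = texture_feature_names()) {
  cv <- cross_val_predict(df, model = model, folds = folds, positive = positive,
                          hyperparams = hyperparams, seed = seed,
                          feature_names = feature_names)
  mean(cv$pred == cv$truth)
}

#' Train and evaluate the decellularization classifiers
#'
#' The full supervised workflow on a per-ROI feature table: stratified
#' train/test split, per-model fit on the training part, held-out test
#' accuracy, pooled 5-fold cross-validated accuracy on the training part,
#' and ROC/AUC on the held-out test scores. Test accuracy and
#' cross-validated accuracy answer different questions and are reported
#' side by side, never merged.
#'
#' @param df Feature table (two classes) with a `label` column.
#' @param models Character vector among `"rf"`, `"svm"`.
#' @param positive Positive-class label (default: the non-`"native"` one).
#' @param train_fraction Training fraction for the split (default 0.8).
#' @param folds Cross-validation folds (default 5).
#' @param seed Master seed for split, folds and fits.
#' @param hyperparams Named list of per-model hyperparameter overrides, e.g.
#'   `list(rf = list(ntree = 200))`.
#' @return An object of class `classifier_report`: a list with `seed`,
#'   `train_fraction`, `folds`, `n_train`, `n_test`, and `models`, a named
#'   list with per-model entries `model_name`, `test_accuracy`,
#'   `cv_accuracy`, `auc`, `roc` (tibble of `fpr`, `tpr`), `hyperparams`.
#' @export
evaluate_classifiers <- function(df, models = c("rf", "svm"), positive = NULL,
                                 train_fraction = 0.8, folds = 5L, seed = 1L,
                                 hyperparams = list()) {
  models <- match.arg(models, several.ok = TRUE)
  pos_label <- if (is.null(positive)) {
    u <- unique(as.character(df$label))
    if ("native" %in% u) setdiff(u, "native") else sort(u)[2]
  } else {
    positive
  }
  parts <- split_train_test(df, train_fraction = train_fraction,
                            stratified = TRUE, seed = seed)
  y_test <- binary_outcome(parts$test$label, positive)
  entries <- lapply(models, function(mo) {
    fit <- fit_texture_classifier(parts$train, model = mo, positive = positive,
                                  hyperparams = hyperparams[[mo]] %||% list(),
                                  seed = seed)
    pred <- predict(fit, parts$test, type = "class")
    scores <- predict(fit, parts$test, type = "score")
    roc <- roc_curve_auc(scores, y_test == "pos")
    cv <- cross_val_accuracy(parts$train, model = mo, folds = folds,
                             positive = positive,
                             hyperparams = hyperparams[[mo]] %||% list(),
                             seed = seed)
    list(
      model_name = mo,
      test_accuracy = mean(as.character(pred) == as.character(y_test)),
      cv_accuracy = cv,
      auc = roc$auc,
      roc = roc$points,
      hyperparams = fit$hyperparams
    )
  })
  names(entries) <- models
  structure(
    list(models = entries, seed = as.integer(seed),
         train_fraction = train_fraction, folds = as.integer(folds),
         n_train = nrow(parts$train), n_test = nrow(parts$test),
         positive = pos_label),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d train / %d test rows, %d-fold CV, seed %d\n",
              x$n_train, x$n_test, x$folds, x$seed))
  print(glance(x))
  invisible(x)
}

#' One row of headline metrics per evaluated model
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `test_accuracy`, `cv_accuracy`,
#'   `auc`.
#' @export
glance.classifier_report <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    tibble::tibble(
      model = m$model_name,
      test_accuracy = m$test_accuracy,
      cv_accuracy = m$cv_accuracy,
      auc = m$auc
    )
  })
}

#' ROC curve points of every evaluated model, in long form
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `threshold`, `fpr`, `tpr`.
#' @export
tidy.classifier_report <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    dplyr::bind_cols(tibble::tibble(model = m$model_name), m$roc)
  })
}

#' Plot the ROC curves of a classifier report
#' @param object A `classifier_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_report <- function(object, ...) {
  df <- tidy(object)
  lab <- glance(object)
  lab$legend <- sprintf("%s (AUC = %.3f)", toupper(lab$model), lab$auc)
  df <- dplyr::left_join(df, lab[, c("model", "legend")], by = "model")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$legend)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  color = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "bottom")
}
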