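#' Validation schemes
#'
#' The two schemes used to assess the models: stratified k-fold
#' cross-validation (default k = 10; folds keep every class's count within
#' one of an even split) and the jackknife (leave-one-out) test, in which
#' each sample is predicted by a model trained on all the others.
#'
#' @param kind `"stratified_kfold"` or `"jackknife"`.
#' @param k Number of folds (ignored for jackknife, where k = n).
#' @param seed Integer seed for the fold shuffle (irrelevant for jackknife).
#' @return A `xyl_scheme` object.
#' @examples
#' validation_scheme("jackknife")
#' @export
validation_scheme <- function(kind = c("stratified_kfold", "jackknife"),
                              k = 10L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "stratified_kfold" && (length(k) != 1 || k < 2)) {
    abort("k must be >= 2", class = "xyl_param_error")
  }
  structure(list(kind = kind, k = as.integer(k), seed = as.integer(seed)),
            class = "xyl_scheme")
}

#' @export
print.xyl_scheme <- function(x, ...) {
  cat(sprintf("<xyl_scheme> %s%s (seed %d)\n", x$kind,
              if (x$kind == "stratified_kfold") paste0(", k = ", x$k) else "", x$seed))
  invisible(x)
}

#' Assign samples to cross-validation folds
#'
#' Jackknife gives each sample its own singleton test fold. Stratified
#' k-fold shuffles within each class (seeded) and deals indices round-robin,
#' so every fold carries either `floor(n_c/k)` or `ceiling(n_c/k)` samples
#' of class `c`. For numeric (regression) targets there is no stratum:
#' samples are shuffled and dealt round-robin.
#'
#' @param y Class labels (factor/character, stratified) or numeric targets
#'   (plain shuffled folds), or a single integer n.
#' @param scheme A [validation_scheme()].
#' @return Integer vector of fold ids (1..k), one per sample.
#' @examples
#' table(make_folds(rep(c("a", "b"), c(12, 8)), validation_scheme(k = 4)))
#' @export
make_folds <- function(y, scheme = validation_scheme()) {
  stopifnot(inherits(scheme, "xyl_scheme"))
  n <- if (length(y) == 1 && is.numeric(y) && y == round(y) && y > 1) as.integer(y) else length(y)
  if (scheme$kind == "jackknife") {
    return(seq_len(n))
  }
  k <- scheme$k
  if (k > n) abort(sprintf("k = %d folds but only n = %d samples", k, n),
                   class = "xyl_param_error")
  folds <- integer(n)
  strata <- if (length(y) == n && (is.factor(y) || is.character(y))) {
    split(seq_len(n), factor(y))
  } else {
    list(seq_len(n))
  }
  withr::with_seed(scheme$seed, {
    offset <- 0L
    for (idx in strata) {
      shuffled <- if (length(idx) > 1) sample(idx) else idx
      folds[shuffled] <- ((offset + seq_along(shuffled) - 1L) %% k) + 1L
      offset <- offset + length(shuffled)
    }
  })
  folds
}

#' Classification metric suite
#'
#' Pooled-prediction metrics for the halo classifier: classification
#' accuracy (CA), and support-weighted per-class precision, recall and F1.
#' AUC is the one-vs-rest area under the ROC curve per class, weighted by
#' class prevalence (multiclass AUC is not uniquely defined; this is the
#' prevalence-weighted convention).
#'
#' @param truth Factor (or character) of true classes.
#' @param predicted Factor of predicted classes, same length.
#' @param scores Matrix or data frame of per-class scores with one column per
#'   class of `truth` (named either by the class or `.score_<class>`), rows
#'   summing to 1. `NULL` skips AUC (returned as `NA`).
#' @return A one-row tibble: `auc`, `ca`, `f1`, `precision`, `recall`.
#' @examples
#' classification_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
#' @export
classification_metrics <- function(truth, predicted, scores = NULL) {
  truth <- factor(truth)
  lev <- levels(truth)
  predicted <- factor(predicted, levels = union(lev, levels(factor(predicted))))
  if (length(truth) != length(predicted)) {
    abort("truth and predicted lengths differ", class = "xyl_dimension_error")
  }
  ca <- mean(as.character(predicted) == as.character(truth))
  per_class <- map(lev, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(class = cl, support = sum(truth == cl), precision = prec, recall = rec, f1 = f1)
  })
  pc <- list_rbind(per_class)
  wts <- pc$support / sum(pc$support)
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(as.data.frame(scores))
    cn <- sub("^\\.score_", "", colnames(scores))
    if (!all(lev %in% cn)) {
      abort(sprintf("scores are missing class column(s): %s",
                    paste(setdiff(lev, cn), collapse = ", ")),
            class = "xyl_score_schema_error")
    }
    aucs <- map_dbl(lev, function(cl) {
      resp <- factor(truth == cl, levels = c(FALSE, TRUE))
      if (length(unique(resp)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(resp, scores[, match(cl, cn)],
                                     levels = c(FALSE, TRUE), direction = "<",
                                     quiet = TRUE)))
    })
    auc <- sum(aucs * wts, na.rm = TRUE) / sum(wts[!is.na(aucs)])
  }
  tibble(
    auc = auc,
    ca = ca,
    f1 = sum(pc$f1 * wts),
    precision = sum(pc$precision * wts),
    recall = sum(pc$recall * wts)
  )
}

#' Regression metric suite
#'
#' Pooled-prediction metrics for the activity regressor: mean squared error,
#' its square root, mean absolute error, and R^2 computed as
#' `1 - SSE / SStot` with `SStot` taken about the mean of all pooled true
#' values. Out-of-sample R^2 under this convention can be negative (a model
#' worse than predicting the global mean).
#'
#' @param truth,predicted Aligned numeric vectors, length >= 2.
#' @return A one-row tibble: `mse`, `rmse`, `mae`, `r2`.
#' @examples
#' regression_metrics(c(0, 0, 3, 3), c(1, 1, 2, 2))
#' @export
regression_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 2) {
    abort("need aligned vectors of length >= 2", class = "xyl_dimension_error")
  }
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) {
    abort("R^2 undefined: true values have zero variance", class = "xyl_degenerate_target_error")
  }
  err <- truth - predicted
  mse <- mean(err^2)
  tibble(mse = mse, rmse = sqrt(mse), mae = mean(abs(err)),
         r2 = 1 - sum(err^2) / ss_tot)
}

#' Cross-validate a model configuration
#'
#' Runs the given validation scheme: for each fold, fits the configured
#' model on the training part and predicts the held-out part, then pools the
#' out-of-fold predictions (exactly one per sample) and computes the metric
#' suite once on the pooled vector.
#'
#' @param features Feature data frame (an `id` column, if present, is carried
#'   into the report).
#' @param y Targets aligned to `features` rows: factor/character for
#'   classifiers, numeric for regressors.
#' @param config A [model_preset()] configuration.
#' @param scheme A [validation_scheme()].
#' @return A `xyl_cv` object; see [tidy()] (per-sample predictions),
#'   [glance()] (one-row metric suite) and [autoplot()].
#' @examples
#' feats <- extract_features(simulate_sequences(sim_config(n_sequences = 30)),
#'                           pseaac_params())
#' y <- rowSums(feats[-1])
#' cv <- cross_validate(feats, y, model_preset("knn_regressor"),
#'                      validation_scheme("jackknife"))
#' glance(cv)
#' @export
cross_validate <- function(features, y, config, scheme = validation_scheme()) {
  stopifnot(inherits(config, "xyl_model_config"), inherits(scheme, "xyl_scheme"))
  ids <- if (is.data.frame(features) && "id" %in% names(features)) {
    as.character(features$id)
  } else {
    as.character(seq_len(nrow(features)))
  }
  X <- feature_matrix(features)
  n <- nrow(X)
  if (n != length(y)) abort("features and y are misaligned", class = "xyl_dimension_error")
  if (config$task == "classify") y <- factor(y)

  fold_of <- make_folds(if (config$task == "classify") y else as.numeric(y), scheme)
  classify <- config$task == "classify"
  lev <- if (classify) levels(y) else NULL

  pred <- if (classify) character(n) else numeric(n)
  # classes absent from a training fold score 0 for the held-out samples
  scores <- if (classify) matrix(0, n, length(lev), dimnames = list(NULL, lev))

  for (f in sort(unique(fold_of))) {
    test <- which(fold_of == f)
    train <- which(fold_of != f)
    cfg <- config
    # derive a per-fold seed from the scheme so repeated runs are identical
    cfg$seed <- (config$seed %||% scheme$seed) + f
    fitted <- tryCatch(
      fit_model(X[train, , drop = FALSE], y[train], cfg),
      error = function(e) abort(sprintf("fold %d: %s", f, conditionMessage(e)),
                                class = class(e)[1], parent = e)
    )
    p <- predict(fitted, X[test, , drop = FALSE])
    if (classify) {
      pred[test] <- as.character(p$.pred_class)
      fit_lev <- sub("^\\.score_", "", grep("^\\.score_", names(p), value = TRUE))
      scores[test, fit_lev] <- as.matrix(p[paste0(".score_", fit_lev)])
    } else {
      pred[test] <- p
    }
  }

  metrics <- if (classify) {
    classification_metrics(y, factor(pred, levels = lev), scores)
  } else {
    regression_metrics(as.numeric(y), pred)
  }

  structure(
    list(
      config = config, scheme = scheme, n = n,
      predictions = bind_cols(
        tibble(id = ids, fold = fold_of,
               truth = if (classify) y else as.numeric(y),
               pred = if (classify) factor(pred, levels = lev) else pred),
        if (classify) as_tibble(`colnames<-`(scores, paste0(".score_", lev)))
      ),
      metrics = metrics
    ),
    class = "xyl_cv"
  )
}

#' @export
print.xyl_cv <- function(x, ...) {
  cat(sprintf("<xyl_cv> %s, %s on %d samples\n", x$config$name, x$scheme$kind, x$n))
  print(x$metrics)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `xyl_cv` object.
#' @param ... Unused.
#' @export
tidy.xyl_cv <- function(x, ...) {
  x$predictions
}

#' @rdname cross_validate
#' @export
glance.xyl_cv <- function(x, ...) {
  bind_cols(
    tibble(model = x$config$name, scheme = x$scheme$kind,
           k = if (x$scheme$kind == "jackknife") x$n else x$scheme$k,
           seed = x$scheme$seed, n = x$n),
    x$metrics
  )
}

#' Plot a cross-validation result
#'
#' Classifiers get a confusion-matrix tile plot of pooled out-of-fold
#' predictions; regressors a predicted-vs-true scatter with the identity
#' line.
#'
#' @param object A `xyl_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.xyl_cv <- function(object, ...) {
  d <- object$predictions
  if (object$config$task == "classify") {
    cm <- dplyr::count(d, .data$truth, .data$pred)
    ggplot2::ggplot(cm, ggplot2::aes(x = .data$pred, y = .data$truth, fill = .data$n)) +
      ggplot2::geom_tile() +
      ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
      ggplot2::labs(x = "predicted class", y = "true class",
                    title = sprintf("%s (%s): pooled out-of-fold confusion",
                                    object$config$name, object$scheme$kind)) +
      ggplot2::guides(fill = "none")
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$pred)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
      ggplot2::geom_point() +
      ggplot2::labs(x = "measured activity (IU/ml)", y = "predicted activity (IU/ml)",
                    title = sprintf("%s (%s)", object$config$name, object$scheme$kind))
  }
}
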