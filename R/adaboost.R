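# AdaBoost.R2 (Drucker-style boosting for regression) over rpart trees.
# Linear loss; each round reweights training rows by relative absolute error
# and the ensemble predicts the weighted median of the member predictions
# (member weight log(1/beta_t)). Fitting is by case weights, not resampling,
# so the whole procedure is deterministic.

adaboost_r2_fit <- function(X, y, n_estimators = 50L, min_leaf = 2L,
                            min_internal = 5L, max_depth = 30L) {
  n <- nrow(X)
  df <- as.data.frame(X)
  df$.y <- as.numeric(y)
  ctrl <- rpart::rpart.control(minsplit = min_internal, minbucket = min_leaf,
                               maxdepth = max_depth, cp = 0, xval = 0)
  w <- rep(1 / n, n)
  trees <- list()
  betas <- numeric(0)
  for (t in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "anova",
                        control = ctrl)
    pred <- predict(fit, df)
    err <- abs(pred - df$.y)
    D <- max(err)
    if (D == 0) { # perfect member: keep it with near-zero beta and stop
      trees <- c(trees, list(fit))
      betas <- c(betas, 1e-10)
      break
    }
    loss <- err / D
    err_bar <- sum(w * loss)
    if (err_bar >= 0.5) {
      if (length(trees) == 0) { # degenerate first round: keep the single tree
        trees <- list(fit)
        betas <- 0.5 / (1 - 0.5 + 1e-12)
      }
      break
    }
    beta <- err_bar / (1 - err_bar)
    trees <- c(trees, list(fit))
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  list(trees = trees, betas = betas, feature_names = colnames(X))
}

adaboost_r2_predict <- function(model, X) {
  df <- as.data.frame(X)
  preds <- vapply(model$trees, function(tr) as.numeric(predict(tr, df)),
                  numeric(nrow(df)))
  preds <- matrix(preds, nrow = nrow(df))
  wts <- log(1 / pmax(model$betas, 1e-12))
  if (all(wts <= 0)) wts <- rep(1, length(wts))
  apply(preds, 1, function(p) {
    ord <- order(p)
    cum <- cumsum(wts[ord])
    p[ord][match(TRUE, cum >= 0.5 * sum(wts))]
  })
}
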