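#' Recompute the study's full results grid
#'
#' Runs every classifier preset (halo L/M/H class, all 41 strains) and every
#' regressor preset (activity in IU/ml, the 28 assayed strains, per
#' condition) under both validation schemes, and returns all metrics in one
#' long table mirroring the study's two results tables.
#'
#' The `exact` flag marks the cells that are deterministic replications when
#' the original feature matrix is supplied: only the KNN x jackknife cells
#' qualify (no randomness anywhere on that path). Every other cell — SVM,
#' AdaBoost, random forest, naive Bayes, and every 10-fold cell — depends on
#' unstated hyperparameters and/or fold/ensemble seeds and is flagged
#' `approximate`; the configuration actually used is carried in the output.
#'
#' @param strains Strain table shaped like [xylanase_strains()].
#' @param features Feature matrix with an `id` column matching
#'   `strains$accession` (e.g. from [extract_features()] or
#'   [read_feature_matrix()]).
#' @param seed Seed for fold shuffles and stochastic learners.
#' @param conditions Condition labels to evaluate (default all three).
#' @return A tibble with columns `task`, `model`, `scheme`, `condition`,
#'   `metric`, `value`, `exact`, `seed`.
#' @export
reproduce_tables <- function(strains, features, seed = 1L,
                             conditions = CONDITION_LABELS) {
  stopifnot(is.data.frame(strains), is.data.frame(features))
  if (!"id" %in% names(features)) {
    abort("`features` needs an `id` column", class = "xyl_schema_error")
  }
  missing_feat <- setdiff(strains$accession, features$id)
  if (length(missing_feat) > 0) {
    abort(sprintf("no features for strain(s): %s", paste(missing_feat, collapse = ", ")),
          class = "xyl_alignment_error")
  }
  feats <- features[match(strains$accession, features$id), , drop = FALSE]

  schemes <- list(
    `10-fold` = validation_scheme("stratified_kfold", k = 10L, seed = seed),
    jackknife = validation_scheme("jackknife", seed = seed)
  )
  classifiers <- c("rf_classifier", "svm_classifier", "knn_classifier", "naive_bayes")
  regressors <- c("svm_regressor", "knn_regressor", "adaboost_regressor", "rf_regressor")

  rows <- list()
  for (model in classifiers) {
    for (sname in names(schemes)) {
      cv <- cross_validate(feats, strains$real_class,
                           model_preset(model, seed = seed), schemes[[sname]])
      m <- tidyr::pivot_longer(cv$metrics, dplyr::everything(),
                               names_to = "metric", values_to = "value")
      rows[[length(rows) + 1]] <- mutate(
        m, task = "classification", model = model, scheme = sname,
        condition = NA_character_,
        exact = model == "knn_classifier" & sname == "jackknife", seed = seed
      )
    }
  }
  assayed <- strains[!is.na(strains[[paste0("act_", conditions[1])]]), ]
  feats_a <- feats[match(assayed$accession, feats$id), , drop = FALSE]
  for (cond in conditions) {
    yv <- assayed[[paste0("act_", cond)]]
    for (model in regressors) {
      for (sname in names(schemes)) {
        cv <- cross_validate(feats_a, yv, model_preset(model, seed = seed),
                             schemes[[sname]])
        m <- tidyr::pivot_longer(cv$metrics, dplyr::everything(),
                                 names_to = "metric", values_to = "value")
        rows[[length(rows) + 1]] <- mutate(
          m, task = "regression", model = model, scheme = sname, condition = cond,
          exact = model == "knn_regressor" & sname == "jackknife", seed = seed
        )
      }
    }
  }
  out <- list_rbind(rows)
  select(out, "task", "model", "scheme", "condition", "metric", "value", "exact", "seed")
}
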