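## Evaluation protocols: confusion summaries with balanced accuracy,
## per-module (applicability-domain) breakdowns, stratified k-fold
## cross-validation with in-fold reweighting and in-fold recomputation of
## the KNN feature, and leave-one-out evaluation.

#' Balanced accuracy from sensitivity and specificity
#'
#' @param sensitivity,specificity Rates (either both percent or both
#'   fractions).
#' @return Their mean, on the same scale.
#' @export
bac <- function(sensitivity, specificity) (sensitivity + specificity) / 2

#' Confusion summary with sensitivity, specificity and balanced accuracy
#'
#' Rates are percentages. A rate whose denominator is zero is undefined and
#' reported as `NA`; by the reporting convention for modules without
#' positives, the balanced accuracy then falls back to the defined rate
#' alone and the `undefined_sensitivity` / `undefined_specificity` flag is
#' set.
#'
#' @param labels,predictions Logical vectors of equal length (truth,
#'   predicted).
#' @param scope Label for the evaluation scope (e.g. `"global"` or a module
#'   id).
#' @return A `confusion_summary` list: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `bac`, `n`, `scope`, undefined-rate
#'   flags.
#' @export
confusion <- function(labels, predictions, scope = "global") {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  if (length(labels) != length(predictions))
    stop("labels and predictions have different lengths", call. = FALSE)
  confusion_from_counts(tp = sum(labels & predictions),
                        fp = sum(!labels & predictions),
                        fn = sum(labels & !predictions),
                        tn = sum(!labels & !predictions),
                        scope = scope)
}

#' @rdname confusion
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, scope = "global") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  b <- if (!is.na(sens) && !is.na(spec)) bac(sens, spec)
       else if (!is.na(spec)) spec
       else sens
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec, bac = b,
                 n = tp + fp + fn + tn, scope = scope,
                 undefined_sensitivity = is.na(sens),
                 undefined_specificity = is.na(spec)),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NAN" else sprintf("%.2f%%", v)
  cat(sprintf("[%s] sens %s  spec %s  BAC %s  (TP %d FP %d FN %d TN %d)\n",
              x$scope, fmt(x$sensitivity), fmt(x$specificity), fmt(x$bac),
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Per-module confusion breakdown
#'
#' Confusion counts and rates restricted to each module, plus an `ALL` row
#' whose counts are the column-wise sums of the module rows.
#'
#' @param labels,predictions Logical vectors.
#' @param modules Module ids aligned with the vectors (`NA` = no module;
#'   such substances are excluded, as only substances with a module
#'   membership define an applicability domain).
#' @return Data frame: `module`, `sensitivity`, `specificity`, `bac` (all
#'   percent, `NA` printed as undefined), `fn`, `tp`, `tn`, `fp`, `total`.
#' @export
module_confusion <- function(labels, predictions, modules) {
  stopifnot(length(labels) == length(predictions),
            length(labels) == length(modules))
  keep <- !is.na(modules)
  labels <- as.logical(labels)[keep]
  predictions <- as.logical(predictions)[keep]
  modules <- modules[keep]
  ids <- sort(unique(modules))
  row_of <- function(cs, name)
    data.frame(module = as.character(name), sensitivity = cs$sensitivity,
               specificity = cs$specificity, bac = cs$bac, fn = cs$fn,
               tp = cs$tp, tn = cs$tn, fp = cs$fp, total = cs$n,
               stringsAsFactors = FALSE)
  rows <- lapply(ids, function(m) {
    i <- modules == m
    row_of(confusion(labels[i], predictions[i],
                     scope = paste0("module:", m)), m)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, row_of(confusion(labels, predictions, scope = "global"),
                           "ALL"))
  rownames(out) <- NULL
  out
}

## Internal: stratified fold assignment preserving class proportions +-1.
stratified_folds <- function(labels, k, seed) {
  labels <- as.logical(labels)
  if (min(sum(labels), sum(!labels)) < k)
    stop(sprintf("each class needs at least k = %d members", k),
         call. = FALSE)
  with_seed(derive_seed(seed, "folds"), {
    fold <- integer(length(labels))
    fold[sample(which(labels))] <- rep_len(seq_len(k), sum(labels))
    fold[sample(which(!labels))] <- rep_len(rev(seq_len(k)), sum(!labels))
    fold
  })
}

## Internal: recompute the KNN feature column for a train/test split so the
## similarity feature never sees held-out labels.
refit_knn_feature <- function(data, train_idx, test_idx, fingerprints,
                              knn_cfg) {
  fp <- as.matrix(fingerprints)
  tr_fp <- fp[train_idx, , drop = FALSE]
  tr_lab <- data$labels[train_idx]
  tr_col <- knn_feature_column(tr_fp, tr_lab, knn_cfg)$knn_prediction
  te_col <- knn_predict_matrix(fp[test_idx, , drop = FALSE], tr_fp, tr_lab,
                               knn_cfg)$knn_prediction
  list(train = tr_col, test = te_col)
}

#' Stratified k-fold cross-validation
#'
#' Folds preserve the class proportions to within one instance. Within each
#' training fold the class-balancing weights are recomputed
#' ([compute_class_weights()]) when `reweight = TRUE`, and -- when
#' fingerprints are supplied and the dataset carries a `KNN` feature -- the
#' KNN column is recomputed against the training fold only (leave-self-out
#' inside the fold for training rows, fold-reference predictions for
#' held-out rows), preventing label leakage through the similarity feature.
#' Without fingerprints an existing KNN column is used as-is (the
#' "replicate-paper" global mode). Held-out predictions are pooled into a
#' single confusion summary; per-fold macro-averaged rates are also
#' returned.
#'
#' @param data A [modeling_dataset()].
#' @param learner Function `function(train_data)` returning a model with a
#'   [predict()] method.
#' @param k Number of folds.
#' @param seed Integer seed for fold assignment.
#' @param reweight Recompute class-balancing weights inside each training
#'   fold.
#' @param fingerprints Optional fingerprint matrix aligned with data rows.
#' @param knn_cfg [knn_config()] used when recomputing the KNN feature.
#' @return List: `predictions` (data frame `substance_id`, `fold`, `label`,
#'   `prediction`), `pooled` (`confusion_summary`), `per_fold` (macro data
#'   frame).
#' @export
stratified_kfold <- function(data, learner, k = 10L, seed = 1L,
                             reweight = TRUE, fingerprints = NULL,
                             knn_cfg = knn_config()) {
  stopifnot(inherits(data, "modeling_dataset"), is.function(learner))
  fold <- stratified_folds(data$labels, k, seed)
  refit_knn <- !is.null(fingerprints) && "KNN" %in% data$feature_names
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    train <- md_subset(data, tr)
    test_feats <- data$features[te, , drop = FALSE]
    if (refit_knn) {
      kc <- refit_knn_feature(data, tr, te, fingerprints, knn_cfg)
      train$features[, "KNN"] <- kc$train
      test_feats[, "KNN"] <- kc$test
    }
    if (reweight)
      train$weights <- compute_class_weights(train$labels)$weights
    model <- learner(train)
    preds[[f]] <- data.frame(substance_id = data$substance_id[te],
                             fold = f, label = data$labels[te],
                             prediction = predict(model, test_feats),
                             stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, preds)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    cs <- confusion(preds$label[preds$fold == f],
                    preds$prediction[preds$fold == f],
                    scope = paste0("fold:", f))
    data.frame(fold = f, sensitivity = cs$sensitivity,
               specificity = cs$specificity, bac = cs$bac, n = cs$n)
  }))
  list(predictions = preds,
       pooled = confusion(preds$label, preds$prediction, scope = "pooled"),
       per_fold = per_fold)
}

#' Leave-one-out evaluation
#'
#' Trains one model per substance on all other substances and predicts the
#' held-out one. With fingerprints supplied and a `KNN` feature present, the
#' KNN column is recomputed for every split exactly as in
#' [stratified_kfold()]. This is the expensive path: a warning is issued
#' above `warn_above` instances.
#'
#' @inheritParams stratified_kfold
#' @param reweight Recompute class-balancing weights on each training set.
#' @param warn_above Instance count above which a cost warning is issued.
#' @return Data frame `substance_id`, `label`, `prediction`.
#' @export
leave_one_out <- function(data, learner, reweight = TRUE,
                          fingerprints = NULL, knn_cfg = knn_config(),
                          warn_above = 500L) {
  stopifnot(inherits(data, "modeling_dataset"), is.function(learner))
  n <- length(data$labels)
  if (n < 2L) stop("leave-one-out needs at least 2 instances", call. = FALSE)
  if (n > warn_above)
    warning(sprintf("leave-one-out will train %d models; this may be slow",
                    n))
  refit_knn <- !is.null(fingerprints) && "KNN" %in% data$feature_names
  pred <- logical(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    train <- md_subset(data, tr)
    test_feats <- data$features[i, , drop = FALSE]
    if (refit_knn) {
      kc <- refit_knn_feature(data, tr, i, fingerprints, knn_cfg)
      train$features[, "KNN"] <- kc$train
      test_feats[, "KNN"] <- kc$test
    }
    if (reweight && length(unique(train$labels)) == 2L)
      train$weights <- compute_class_weights(train$labels)$weights
    pred[i] <- predict(learner(train), test_feats)
  }
  data.frame(substance_id = data$substance_id, label = data$labels,
             prediction = pred, stringsAsFactors = FALSE)
}

#' Write an evaluation table
#'
#' Writes a per-module confusion data frame (or any evaluation data frame)
#' as TSV with two-decimal percentages.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @export
write_evaluation_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    names(df) %in% c("sensitivity", "specificity", "bac")
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "NAN",
                                                sprintf("%.2f", v)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
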