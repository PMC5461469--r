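test_that("confusion rates and balanced accuracy follow the definitions", {
  expect_equal(bac(53.7, 89.1), 71.4)
  cs <- confusion_from_counts(tp = 44, fp = 33, fn = 68, tn = 470)
  expect_equal(round(cs$sensitivity, 2), 39.29)
  expect_equal(round(cs$specificity, 2), 93.44)
  expect_equal(round(cs$bac, 2), 66.36)
  expect_equal(cs$n, 615)

  perfect <- confusion(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$bac, 100)
  expect_equal(perfect$fn + perfect$fp, 0)

  ## zero positives: sensitivity undefined, BAC falls back to specificity
  none <- confusion(rep(FALSE, 45), rep(FALSE, 45))
  expect_true(none$undefined_sensitivity)
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 100)
  expect_equal(none$bac, 100)

  expect_error(confusion(c(TRUE, FALSE), TRUE), "lengths")
})

test_that("balanced accuracy is invariant under class relabeling", {
  set.seed(31)
  for (i in 1:10) {
    lab <- runif(40) < 0.4; pred <- runif(40) < 0.5
    a <- confusion(lab, pred); b <- confusion(!lab, !pred)
    expect_equal(a$bac, b$bac)
    ## and swapping (tp,fn) with (tn,fp) directly
    d <- confusion_from_counts(a$tn, a$fn, a$fp, a$tp)
    expect_equal(d$bac, a$bac)
  }
})

test_that("module rows sum to the ALL row", {
  set.seed(5)
  lab <- runif(120) < 0.3; pred <- runif(120) < 0.4
  mods <- sample(0:4, 120, replace = TRUE)
  mc <- module_confusion(lab, pred, mods)
  all_row <- mc[mc$module == "ALL", ]
  per <- mc[mc$module != "ALL", ]
  for (col in c("fn", "tp", "tn", "fp", "total"))
    expect_equal(sum(per[[col]]), all_row[[col]])
  ## substances without a module are excluded
  mods[1:10] <- NA
  mc2 <- module_confusion(lab, pred, mods)
  expect_equal(mc2$total[mc2$module == "ALL"], 110)
})

test_that("stratified folds preserve balance and partition the data", {
  labels <- rep(c(TRUE, FALSE), each = 100)
  desc <- data.frame(substance_id = sprintf("S%03d", 1:200),
                     f1 = rnorm(200))
  md <- modeling_dataset(desc, labels)
  out <- stratified_kfold(md, majority_learner, k = 10, seed = 3,
                          reweight = FALSE)
  tab <- table(out$predictions$fold, out$predictions$label)
  expect_true(all(tab == 10))                     # 10 + 10 per fold
  expect_identical(sort(out$predictions$substance_id), md$substance_id)
  expect_equal(out$pooled$n, 200)                 # pooled counts conserved
  expect_equal(sum(out$per_fold$n), 200)
  expect_error(stratified_kfold(md, majority_learner, k = 150, seed = 1),
               "at least k")
})

test_that("cross-validated accuracy sits below training accuracy", {
  ## noisier labels give the perceptron room to overfit
  cfg <- generator_config(seed = 51, module_sizes = rep(50L, 9),
                          clustering_strength = 0.65)
  d <- generate_dossier(cfg)
  labels <- d$substances$toxic
  knn <- knn_feature_column(d$fingerprints, labels)
  md <- modeling_dataset(d$descriptors, labels, knn = knn$knn_prediction,
                         weights = compute_class_weights(labels)$weights)
  pcfg <- perceptron_config(epochs = 200, seed = 7)
  train_bac <- confusion(labels,
                         predict(train_perceptron(md, pcfg), md))$bac
  cv <- stratified_kfold(md, function(x) train_perceptron(x, pcfg),
                         k = 5, seed = 11, fingerprints = d$fingerprints)
  expect_gt(train_bac, cv$pooled$bac)
})

test_that("leave-one-out handles the degenerate pair and ignores order", {
  md <- modeling_dataset(data.frame(substance_id = c("A", "B"),
                                    f1 = c(0, 1)), c(TRUE, FALSE))
  out <- leave_one_out(md, majority_learner, reweight = FALSE)
  ## each instance is predicted from the single other one
  expect_identical(out$prediction, c(FALSE, TRUE))

  set.seed(2)
  desc <- data.frame(substance_id = sprintf("S%02d", 1:30), f1 = rnorm(30))
  labels <- rep(c(TRUE, FALSE), 15)
  md2 <- modeling_dataset(desc, labels)
  base <- leave_one_out(md2, majority_learner, reweight = FALSE)
  perm <- sample(30)
  shuf <- leave_one_out(oraltox:::md_subset(md2, perm), majority_learner,
                        reweight = FALSE)
  expect_identical(shuf$prediction[match(base$substance_id,
                                         shuf$substance_id)],
                   base$prediction)
  expect_warning(
    leave_one_out(md2, majority_learner, reweight = FALSE, warn_above = 10),
    "slow")
})

test_that("leave-one-out perceptron recovers sensitivity the KNN misses", {
  ## per-module mean sensitivity, averaged over seeds: the reweighted
  ## perceptron fused with the KNN feature finds toxicants that the
  ## unweighted similarity vote alone misses
  sens <- vapply(1:10, function(seed) {
    cfg <- generator_config(seed = 600 + seed, module_sizes = rep(20L, 9),
                            clustering_strength = 0.8)
    d <- generate_dossier(cfg)
    labels <- d$substances$toxic
    if (sum(labels) < 5 || sum(!labels) < 5) return(c(NA, NA))
    knn <- knn_feature_column(d$fingerprints, labels)
    md <- modeling_dataset(d$descriptors, labels, knn = knn$knn_prediction)
    sg <- detect_modules(build_graph(d$fingerprints, 0.7), seed = 1)
    mods <- unname(sg$module_of[d$substances$substance_id])
    knn_m <- module_confusion(labels, knn$knn_prediction == 1L, mods)
    loo <- leave_one_out(
      md, function(x) train_perceptron(x, perceptron_config(epochs = 100,
                                                            seed = 2)),
      warn_above = 1000L)
    mlp_m <- module_confusion(loo$label, loo$prediction, mods)
    c(mean(knn_m$sensitivity[knn_m$module != "ALL"], na.rm = TRUE),
      mean(mlp_m$sensitivity[mlp_m$module != "ALL"], na.rm = TRUE))
  }, numeric(2))
  expect_gt(mean(sens[2, ], na.rm = TRUE), mean(sens[1, ], na.rm = TRUE))
})

test_that("evaluation tables print NAN for undefined rates", {
  mc <- module_confusion(c(FALSE, FALSE, TRUE, TRUE),
                         c(FALSE, FALSE, TRUE, FALSE), c(0, 0, 1, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_table(mc, path)
  txt <- readLines(path)
  expect_true(any(grepl("NAN", txt)))
})
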