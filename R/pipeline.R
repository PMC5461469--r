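## End-to-end orchestration: generate (or ingest) a dossier dataset, build
## the similarity graph and modules, run the KNN and fused supervised
## models, the feature-importance protocols and the concordance analyses,
## and write the report bundle with a manifest of every filter-stage count.

#' Pipeline configuration
#'
#' Collects the thresholds, model configurations and the master seed of a
#' full pipeline run. Either `generator` (synthetic mode) or `input_dir`
#' (ingest mode pointing at the interchange files written by
#' [write_dossier()]) provides the data.
#'
#' @param seed Master seed; overrides the generator seed so one integer
#'   reproduces the whole run.
#' @param generator A [generator_config()] for synthetic mode.
#' @param input_dir Directory with `studies.csv`, `fingerprints.fp`,
#'   `descriptors.csv`, `hazards.csv` for ingest mode (`NULL` = synthetic).
#' @param ld50_threshold,noael_threshold,taylor_threshold Analysis
#'   thresholds in mg/kg b.w.
#' @param similarity_threshold Edge threshold of the similarity graph.
#' @param knn A [knn_config()].
#' @param perceptron A [perceptron_config()].
#' @param cv_folds Folds for the stratified cross-validation.
#' @param importance_subsets Balanced subsets for the importance protocols
#'   (0 skips them).
#' @param loo_max_n Cap on instances for the leave-one-out perceptron
#'   (0 skips it; above the cap a class-stratified subsample of this size
#'   is evaluated).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, generator = generator_config(),
                            input_dir = NULL,
                            ld50_threshold = 2000, noael_threshold = 200,
                            taylor_threshold = 1000,
                            similarity_threshold = 0.7,
                            knn = knn_config(), perceptron = perceptron_config(),
                            cv_folds = 10L, importance_subsets = 100L,
                            loo_max_n = 0L) {
  stopifnot(ld50_threshold > 0, noael_threshold > 0, taylor_threshold > 0,
            similarity_threshold >= 0, similarity_threshold <= 1)
  generator$seed <- as.integer(seed)
  perceptron$seed <- derive_seed(seed, "model")
  structure(list(seed = as.integer(seed), generator = generator,
                 input_dir = input_dir, ld50_threshold = ld50_threshold,
                 noael_threshold = noael_threshold,
                 taylor_threshold = taylor_threshold,
                 similarity_threshold = similarity_threshold,
                 knn = knn, perceptron = perceptron,
                 cv_folds = as.integer(cv_folds),
                 importance_subsets = as.integer(importance_subsets),
                 loo_max_n = as.integer(loo_max_n)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Every top-level key of [pipeline_config()] can be set; `generator`,
#' `knn` and `perceptron` are nested maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("generator", "knn", "perceptron"))]
  if (!is.null(y$generator))
    args$generator <- do.call(generator_config, y$generator)
  if (!is.null(y$knn)) args$knn <- do.call(knn_config, y$knn)
  if (!is.null(y$perceptron))
    args$perceptron <- do.call(perceptron_config, y$perceptron)
  do.call(pipeline_config, args)
}

## Internal: load an ingested dossier from interchange files.
ingest_dossier <- function(dir) {
  paths <- file.path(dir, c("studies.csv", "fingerprints.fp",
                            "descriptors.csv", "hazards.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("ingest mode: missing input file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  studies <- read_study_table(paths[1L])
  list(acute_studies = studies[studies$endpoint == "acute_oral", ],
       repeated_studies = studies[studies$endpoint != "acute_oral", ],
       fingerprints = read_fingerprints(paths[2L]),
       descriptors = read_descriptors(paths[3L]),
       hazards = as_hazard_table(read.table(paths[4L], header = TRUE,
                                            sep = ",",
                                            stringsAsFactors = FALSE)),
       paths = paths)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on synthetic or ingested data and, when `out_dir`
#' is given, writes the report bundle: study-level exports, graph tables,
#' KNN predictions, per-module evaluation tables, the importance report,
#' the concordance summaries, a `summary.json` of all derived statistics
#' and a `manifest.json` recording configuration, input checksums and the
#' substance count at every filter stage. Identical configuration and seed
#' give an identical bundle.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to only return results.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with every intermediate and final result.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = cfg$seed, counts = list(), inputs = list())

  ## -- data ------------------------------------------------------------
  if (is.null(cfg$input_dir)) {
    say("generating synthetic dossier (seed %d)", cfg$seed)
    dossier <- generate_dossier(cfg$generator)
    acute <- dossier$acute_studies
    repeated <- dossier$repeated_studies
    fingerprints <- dossier$fingerprints
    descriptors <- dossier$descriptors
    hazards <- dossier$hazards
    manifest$mode <- "synthetic"
  } else {
    say("ingesting dossier from %s", cfg$input_dir)
    ing <- ingest_dossier(cfg$input_dir)
    acute <- ing$acute_studies; repeated <- ing$repeated_studies
    fingerprints <- ing$fingerprints; descriptors <- ing$descriptors
    hazards <- ing$hazards
    manifest$mode <- "ingest"
    manifest$inputs <- lapply(setNames(ing$paths, basename(ing$paths)),
                              function(p) unname(tools::md5sum(p)))
  }
  manifest$counts$acute_studies <- nrow(acute)
  manifest$counts$repeated_studies <- nrow(repeated)

  ## -- substance-level labels (Klimisch-1 acute aggregation) -----------
  k1 <- function(df) df$klimisch == 1L
  agg <- aggregate_endpoints(acute, filter = k1, endpoint = "acute_oral")
  agg$toxicant <- label_toxicant(agg, cfg$ld50_threshold)
  ids <- intersect(agg$substance_id,
                   intersect(rownames(fingerprints),
                             descriptors$substance_id))
  agg <- agg[match(ids, agg$substance_id), ]
  fp <- fingerprints[ids, , drop = FALSE]
  desc <- descriptors[match(ids, descriptors$substance_id), , drop = FALSE]
  labels <- agg$toxicant
  manifest$counts$modeled_substances <- length(ids)
  manifest$counts$positives <- sum(labels)
  manifest$counts$negatives <- sum(!labels)
  say("%d modeled substances (%d positive / %d negative)",
      length(ids), sum(labels), sum(!labels))

  ## -- similarity graph and modules -------------------------------------
  sg <- build_graph(fp, cfg$similarity_threshold)
  sg <- detect_modules(sg, seed = derive_seed(cfg$seed, "modules"))
  modules <- unname(sg$module_of[ids])
  manifest$counts$graph_edges <- igraph::ecount(sg$graph)
  manifest$counts$modules <- length(unique(modules))
  say("graph: %d edges, %d modules, Q = %.3f",
      igraph::ecount(sg$graph), length(unique(modules)), sg$q)

  ## -- KNN --------------------------------------------------------------
  knn_col <- knn_feature_column(fp, labels, cfg$knn)
  knn_global <- confusion(labels, knn_col$knn_prediction == 1L,
                          scope = "knn_global")
  knn_modules <- module_confusion(labels, knn_col$knn_prediction == 1L,
                                  modules)

  ## -- fused supervised models ------------------------------------------
  cw <- compute_class_weights(labels, mode = "paper")
  data <- modeling_dataset(desc, labels, knn = knn_col$knn_prediction,
                           weights = ifelse(labels, cw$factor, 1))
  tree <- train_decision_tree(data)
  tree_train <- confusion(labels, predict(tree, data), scope = "tree_train")
  mlp <- train_perceptron(data, cfg$perceptron)
  mlp_train_eval <- confusion(labels, predict(mlp, data),
                              scope = "perceptron_train")
  say("running %d-fold cross-validation", cfg$cv_folds)
  cv <- stratified_kfold(data,
                         function(d) train_perceptron(d, cfg$perceptron),
                         k = cfg$cv_folds,
                         seed = derive_seed(cfg$seed, "folds"),
                         reweight = TRUE, fingerprints = fp,
                         knn_cfg = cfg$knn)
  mlp_modules <- NULL
  loo <- NULL
  if (cfg$loo_max_n > 0L) {
    idx <- seq_along(labels)
    if (length(idx) > cfg$loo_max_n) {
      idx <- with_seed(derive_seed(cfg$seed, "loo"), {
        n_pos <- round(cfg$loo_max_n * mean(labels))
        c(sample(which(labels), n_pos),
          sample(which(!labels), cfg$loo_max_n - n_pos))
      })
      idx <- sort(idx)
    }
    say("leave-one-out perceptron on %d substances", length(idx))
    loo <- leave_one_out(md_subset(data, idx),
                         function(d) train_perceptron(d, cfg$perceptron),
                         reweight = TRUE,
                         fingerprints = fp[idx, , drop = FALSE],
                         knn_cfg = cfg$knn, warn_above = .Machine$integer.max)
    mlp_modules <- module_confusion(loo$label, loo$prediction, modules[idx])
  }

  ## -- feature importance ------------------------------------------------
  importance <- NULL
  if (cfg$importance_subsets > 0L) {
    say("importance protocols over %d balanced subsets",
        cfg$importance_subsets)
    importance <- importance_report(data, cfg$importance_subsets,
                                    seed = derive_seed(cfg$seed, "subsets"))
  }

  ## -- concordance analyses ----------------------------------------------
  all_studies <- rbind(as.data.frame(acute), as.data.frame(repeated))
  prevalence <- hazard_prevalence(hazards)
  agreement <- guideline_agreement(acute, cfg$ld50_threshold)
  bulgheroni_all <- bulgheroni_table(all_studies, cfg$noael_threshold,
                                     cfg$ld50_threshold, "all")
  bulgheroni_key <- bulgheroni_table(all_studies, cfg$noael_threshold,
                                     cfg$ld50_threshold, "key_only")
  pairs <- matched_noael_pairs(all_studies)
  taylor <- taylor_filter(all_studies, hazards, cfg$taylor_threshold)
  predictivity <- taylor_predictivity(pairs, cfg$taylor_threshold,
                                      constrained = taylor$substance_id)
  key_pairs <- matched_noael_pairs(all_studies,
                                   filter = function(df) df$key_study)
  factor3 <- if (nrow(key_pairs)) factor3_check(key_pairs) else NULL
  manifest$counts$noael_pairs <- nrow(pairs)
  manifest$counts$taylor_substances <- nrow(taylor)

  results <- list(config = cfg, manifest = manifest,
                  substances = data.frame(substance_id = ids,
                                          toxicant = labels,
                                          module = modules,
                                          stringsAsFactors = FALSE),
                  graph = sg, knn = knn_col, knn_global = knn_global,
                  knn_modules = knn_modules, class_weights = cw,
                  tree = tree, tree_train = tree_train,
                  perceptron = mlp, perceptron_train = mlp_train_eval,
                  cv = cv, loo = loo, perceptron_modules = mlp_modules,
                  importance = importance, prevalence = prevalence,
                  agreement = agreement,
                  bulgheroni_all = bulgheroni_all,
                  bulgheroni_key = bulgheroni_key,
                  taylor = predictivity, factor3 = factor3)

  if (!is.null(out_dir)) write_report_bundle(results, out_dir)
  invisible(results)
}

## Internal: serialize the report bundle.
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  write.table(res$substances, f("substances.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_graph_tables(res$graph, f("graph_edges.tsv"), f("graph_modules.tsv"))
  write.table(res$knn, f("knn_predictions.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_evaluation_table(res$knn_modules, f("knn_modules.tsv"))
  if (!is.null(res$perceptron_modules))
    write_evaluation_table(res$perceptron_modules,
                           f("perceptron_modules.tsv"))
  if (!is.null(res$importance))
    write_importance_report(res$importance, f("importance.tsv"))
  write.table(res$prevalence, f("hazard_prevalence.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  agree <- matrix(sprintf("%s%% (%d)",
                          ifelse(is.na(res$agreement$percent), "-",
                                 format(res$agreement$percent)),
                          res$agreement$n),
                  nrow = nrow(res$agreement$percent),
                  dimnames = dimnames(res$agreement$percent))
  write.table(agree, f("guideline_agreement.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  for (scope in c("all", "key")) {
    b <- res[[paste0("bulgheroni_", scope)]]
    write.table(b$table, f(sprintf("bulgheroni_%s.tsv", scope)), sep = "\t",
                quote = FALSE, col.names = NA)
  }
  cs_list <- function(cs) cs[c("tp", "fp", "fn", "tn", "sensitivity",
                               "specificity", "bac", "n")]
  summary <- list(
    class_weight_factor = res$class_weights$factor,
    knn_global = cs_list(res$knn_global),
    tree_train = cs_list(res$tree_train),
    perceptron_train = cs_list(res$perceptron_train),
    perceptron_cv = cs_list(res$cv$pooled),
    bulgheroni_all = res$bulgheroni_all[c("npv", "ppv", "avoidable_count",
                                          "n")],
    bulgheroni_key = res$bulgheroni_key[c("npv", "ppv", "avoidable_count",
                                          "n")],
    nontoxic_complement = tryCatch(nontoxic_complement(res$prevalence),
                                   error = function(e) NULL),
    taylor = res$taylor, factor3 = res$factor3,
    modularity_q = res$graph$q)
  jsonlite::write_json(summary, f("summary.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows", na = "null")
  jsonlite::write_json(res$manifest, f("manifest.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(out_dir)
}
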