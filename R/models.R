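## Supervised learners over the molecular descriptors plus the KNN
## similarity feature: instance reweighting, a weighted entropy decision
## tree, and a one-hidden-layer multilayer perceptron trained by online
## backpropagation with momentum.

#' Class-balancing instance weights
#'
#' Gives every toxicant a weight equal to the negative/positive count ratio
#' and every non-toxicant weight 1, so the total weight of the two classes
#' is (exactly, or to two decimals in `"paper"` mode) equal. The published
#' convention reports the factor rounded to two decimals, e.g. a 268/791
#' split gives 2.95.
#'
#' @param labels Logical (or 0/1) toxicant labels with both classes present.
#' @param mode `"exact"` (default; weighted class totals equal to machine
#'   precision) or `"paper"` (factor rounded to 2 decimals first).
#' @return List with `factor` and per-instance `weights`.
#' @export
compute_class_weights <- function(labels, mode = c("exact", "paper")) {
  mode <- match.arg(mode)
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute class weights",
         call. = FALSE)
  factor <- n_neg / n_pos
  if (mode == "paper") factor <- round(factor, 2L)
  list(factor = factor, weights = ifelse(labels, factor, 1))
}

#' Assemble a modelling dataset
#'
#' Binds the descriptor columns (and optionally the KNN similarity feature)
#' into a feature matrix aligned with labels and instance weights. Missing
#' feature values are rejected: modelled substances must have complete
#' descriptor vectors.
#'
#' @param descriptors Descriptor data frame with `substance_id` plus numeric
#'   columns (see [descriptor_names()]).
#' @param labels Logical toxicant labels aligned with `descriptors` rows.
#' @param knn Optional 0/1 KNN feature column (from [knn_feature_column()]),
#'   added as feature `"KNN"`.
#' @param weights Optional positive per-instance weights (default 1).
#' @return A `modeling_dataset`: list with `features` (numeric matrix),
#'   `labels`, `weights`, `substance_id`, `feature_names`.
#' @export
modeling_dataset <- function(descriptors, labels, knn = NULL,
                             weights = NULL) {
  stopifnot(is.data.frame(descriptors), "substance_id" %in% names(descriptors))
  ids <- as.character(descriptors$substance_id)
  feats <- descriptors[setdiff(names(descriptors), "substance_id")]
  feats <- as.matrix(feats)
  storage.mode(feats) <- "double"
  if (!is.null(knn)) {
    knn <- as.numeric(knn)
    stopifnot(length(knn) == nrow(feats))
    feats <- cbind(feats, KNN = knn)
  }
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(feats))
  if (anyNA(feats) || any(!is.finite(feats)))
    stop("modelling dataset has missing or non-finite feature values",
         call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(feats))
  stopifnot(length(weights) == nrow(feats), all(weights > 0))
  structure(list(features = feats, labels = labels, weights = weights,
                 substance_id = ids, feature_names = colnames(feats)),
            class = "modeling_dataset")
}

## Internal: subset a modeling_dataset by row index.
md_subset <- function(data, idx) {
  structure(list(features = data$features[idx, , drop = FALSE],
                 labels = data$labels[idx], weights = data$weights[idx],
                 substance_id = data$substance_id[idx],
                 feature_names = data$feature_names),
            class = "modeling_dataset")
}

## Internal: strict feature-schema check for prediction inputs.
check_schema <- function(model_features, newdata) {
  nd_names <- colnames(newdata)
  if (is.null(nd_names) ||
      !identical(sort(nd_names), sort(model_features)))
    stop("feature schema mismatch: model expects exactly {",
         paste(model_features, collapse = ", "), "}", call. = FALSE)
  as.matrix(newdata[, model_features, drop = FALSE])
}

#' Train a weighted decision tree
#'
#' Fits a binary classification tree with the entropy (information) split
#' criterion and per-instance weights, through \pkg{rpart}. The default
#' depth of 2 matches the two-feature fused tree of interest: split first on
#' the KNN similarity feature, then on the next most informative descriptor.
#'
#' @param data A [modeling_dataset()].
#' @param features Character vector of feature names to use (default: all).
#' @param max_depth Maximum tree depth.
#' @return An `oraltox_tree` model.
#' @export
train_decision_tree <- function(data, features = NULL, max_depth = 2L) {
  stopifnot(inherits(data, "modeling_dataset"))
  if (is.null(features)) features <- data$feature_names
  if (length(features) == 0L)
    stop("empty feature list", call. = FALSE)
  missing <- setdiff(features, data$feature_names)
  if (length(missing))
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(data$features[, features, drop = FALSE])
  df$.class <- factor(ifelse(data$labels, "pos", "neg"),
                      levels = c("neg", "pos"))
  fit <- rpart::rpart(.class ~ ., data = df, weights = data$weights,
                      method = "class",
                      parms = list(split = "information"),
                      control = rpart::rpart.control(
                        maxdepth = max_depth, cp = 0, minsplit = 2L,
                        minbucket = 1L, xval = 0L))
  structure(list(fit = fit, feature_names = features),
            class = "oraltox_tree")
}

#' @export
predict.oraltox_tree <- function(object, newdata, ...) {
  if (inherits(newdata, "modeling_dataset")) newdata <- newdata$features
  x <- check_schema(object$feature_names, newdata)
  cls <- predict(object$fit, as.data.frame(x), type = "class")
  unname(cls == "pos")
}

#' Multilayer perceptron configuration
#'
#' Numeric defaults of the conventional toolkit configuration: one hidden
#' sigmoid layer with `ceiling((n_features + n_classes) / 2)` units,
#' learning rate 0.3, momentum 0.2, 500 epochs of online backpropagation.
#' `hidden_units = NULL` defers the layer size to the training data.
#'
#' @param hidden_units Hidden layer size, or `NULL` for the default rule.
#' @param learning_rate,momentum,epochs Backpropagation parameters.
#' @param seed Integer seed for the weight initialisation.
#' @return A `perceptron_config` list.
#' @export
perceptron_config <- function(hidden_units = NULL, learning_rate = 0.3,
                              momentum = 0.2, epochs = 500L, seed = 1L) {
  stopifnot(learning_rate >= 0, momentum >= 0, epochs >= 1L)
  structure(list(hidden_units = hidden_units, learning_rate = learning_rate,
                 momentum = momentum, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "perceptron_config")
}

#' Train a multilayer perceptron
#'
#' One hidden sigmoid layer, two sigmoid output units with one-hot targets
#' and squared-error loss, trained by weighted online gradient descent with
#' momentum, instances visited in row order. Features are standardized to
#' zero mean / unit variance before training (descriptors span orders of
#' magnitude); the standardization statistics are stored with the model and
#' reused at prediction time. Training is deterministic under the
#' configuration seed.
#'
#' @param data A [modeling_dataset()].
#' @param cfg A [perceptron_config()].
#' @return An `oraltox_perceptron` model.
#' @export
train_perceptron <- function(data, cfg = perceptron_config()) {
  stopifnot(inherits(data, "modeling_dataset"),
            inherits(cfg, "perceptron_config"))
  x <- data$features
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite feature values", call. = FALSE)
  mu <- colMeans(x)
  sig <- apply(x, 2L, sd)
  sig[sig == 0 | is.na(sig)] <- 1          # constant features pass through
  xs <- sweep(sweep(x, 2L, mu), 2L, sig, "/")
  p <- ncol(xs)
  h <- if (is.null(cfg$hidden_units)) ceiling((p + 2L) / 2L) else
    as.integer(cfg$hidden_units)
  init <- with_seed(cfg$seed, list(
    W1 = matrix(runif(h * p, -0.5, 0.5), nrow = h),
    b1 = runif(h, -0.5, 0.5),
    W2 = matrix(runif(2L * h, -0.5, 0.5), nrow = 2L),
    b2 = runif(2L, -0.5, 0.5)))
  trained <- mlp_train_cpp(xs, as.integer(data$labels), data$weights,
                           init$W1, init$b1, init$W2, init$b2,
                           cfg$learning_rate, cfg$momentum, cfg$epochs)
  structure(list(W1 = trained$W1, b1 = trained$b1, W2 = trained$W2,
                 b2 = trained$b2, center = mu, scale = sig,
                 feature_names = data$feature_names, config = cfg),
            class = "oraltox_perceptron")
}

#' @export
predict.oraltox_perceptron <- function(object, newdata, type = "class", ...) {
  if (inherits(newdata, "modeling_dataset")) newdata <- newdata$features
  x <- check_schema(object$feature_names, newdata)
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  hid <- 1 / (1 + exp(-(xs %*% t(object$W1) +
                          matrix(object$b1, nrow(xs), length(object$b1),
                                 byrow = TRUE))))
  out <- 1 / (1 + exp(-(hid %*% t(object$W2) +
                          matrix(object$b2, nrow(xs), 2L, byrow = TRUE))))
  if (type == "prob") return(out[, 2L] / rowSums(out))
  unname(out[, 2L] > out[, 1L])            # class with the larger output
}

#' Serialize and restore a perceptron model
#'
#' Writes the model to a versioned JSON text file: feature schema,
#' standardization statistics, layer weights and training configuration.
#' The round trip restores a model that predicts identically.
#'
#' @param model An `oraltox_perceptron`.
#' @param path Output/input file path.
#' @return `write_perceptron()` the path invisibly; `read_perceptron()` the
#'   restored model.
#' @export
write_perceptron <- function(model, path) {
  stopifnot(inherits(model, "oraltox_perceptron"))
  obj <- list(format = "oraltox_perceptron", version = 1L,
              feature_names = model$feature_names,
              center = unname(model$center), scale = unname(model$scale),
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_perceptron
#' @export
read_perceptron <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "oraltox_perceptron"))
    stop("not a serialized perceptron model: ", path, call. = FALSE)
  cfg <- obj$config
  cfg$hidden_units <- if (is.null(cfg$hidden_units)) NULL else
    as.integer(cfg$hidden_units)
  structure(list(W1 = as.matrix(obj$W1), b1 = as.numeric(obj$b1),
                 W2 = as.matrix(obj$W2), b2 = as.numeric(obj$b2),
                 center = setNames(as.numeric(obj$center),
                                   obj$feature_names),
                 scale = setNames(as.numeric(obj$scale), obj$feature_names),
                 feature_names = obj$feature_names,
                 config = structure(cfg, class = "perceptron_config")),
            class = "oraltox_perceptron")
}
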