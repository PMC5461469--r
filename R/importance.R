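## Feature-importance protocols over balanced sub-datasets: information-gain
## ranking (Ranker) and held-out decision-tree wrapper selection
## (WrapperEval), both run across 100 class-balanced subsets of the data.

entropy_bits <- function(y) {
  p <- table(y)
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

#' Fayyad--Irani MDL cut points for a continuous feature
#'
#' Recursive entropy-based binary splitting with the minimum description
#' length stopping criterion: a candidate cut is accepted only when its
#' information gain exceeds the MDL cost of encoding it. Returns the sorted
#' accepted cut points (possibly none, in which case the feature carries no
#' accepted information about the labels).
#'
#' @param x Numeric feature vector.
#' @param y Class labels.
#' @return Numeric vector of cut points (may be empty).
#' @export
mdl_cuts <- function(x, y) {
  ok <- !is.na(x)
  x <- x[ok]; y <- as.character(y)[ok]
  recurse <- function(x, y) {
    n <- length(y)
    if (n < 2L) return(numeric())
    ord <- order(x)
    x <- x[ord]; y <- y[ord]
    ux <- unique(x)
    if (length(ux) < 2L) return(numeric())
    cands <- (ux[-1L] + ux[-length(ux)]) / 2
    base_h <- entropy_bits(y)
    best_gain <- -Inf; best_cut <- NA_real_; best_split <- NULL
    for (cut in cands) {
      left <- x <= cut
      nl <- sum(left); nr <- n - nl
      h <- (nl * entropy_bits(y[left]) + nr * entropy_bits(y[!left])) / n
      gain <- base_h - h
      if (gain > best_gain) {
        best_gain <- gain; best_cut <- cut; best_split <- left
      }
    }
    k  <- length(unique(y))
    k1 <- length(unique(y[best_split])); k2 <- length(unique(y[!best_split]))
    delta <- log2(3^k - 2) -
      (k * base_h - k1 * entropy_bits(y[best_split]) -
         k2 * entropy_bits(y[!best_split]))
    threshold <- (log2(n - 1) + delta) / n
    if (best_gain <= threshold) return(numeric())
    sort(c(recurse(x[best_split], y[best_split]),
           best_cut,
           recurse(x[!best_split], y[!best_split])))
  }
  recurse(x, y)
}

#' Information gain of a feature about binary labels
#'
#' `H(labels) - H(labels | feature)`, in bits. Discrete features (logical,
#' factor, character, or numeric with at most two distinct values) use their
#' values as bins; continuous features are discretized first by
#' Fayyad--Irani MDL binning on the same data, so a feature whose best cut
#' fails the MDL criterion scores 0. Constant labels score 0 by convention.
#'
#' @param x Feature vector.
#' @param y Binary labels.
#' @return Information gain, a non-negative number of bits.
#' @export
information_gain <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(y[!is.na(y)])) < 2L) return(0)
  if (is.numeric(x) && length(unique(x[!is.na(x)])) > 2L) {
    cuts <- mdl_cuts(x, y)
    if (!length(cuts)) return(0)
    x <- cut(x, breaks = c(-Inf, cuts, Inf))
  }
  n <- length(y)
  h0 <- entropy_bits(y)
  bins <- split(y, as.character(x))
  h1 <- sum(vapply(bins, function(b) length(b) * entropy_bits(b),
                   numeric(1))) / n
  max(0, h0 - h1)
}

#' Partition a dataset into class-balanced subsets
#'
#' Splits the instances into `n_subsets` subsets of (as near as divisibility
#' allows) equal size, each preserving the global toxicant/non-toxicant
#' balance to within one instance. Every instance appears in exactly one
#' subset; the assignment is deterministic under `seed`.
#'
#' @param labels Logical class labels.
#' @param n_subsets Number of subsets (both classes must have at least this
#'   many members).
#' @param seed Integer seed.
#' @return List of integer index vectors, one per subset.
#' @export
make_balanced_subsets <- function(labels, n_subsets = 100L, seed = 1L) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (min(n_pos, n_neg) < n_subsets)
    stop(sprintf(paste0("need at least %d instances of each class for %d ",
                        "balanced subsets (have %d positive, %d negative)"),
                 n_subsets, n_subsets, n_pos, n_neg), call. = FALSE)
  with_seed(derive_seed(seed, "subsets"), {
    pos <- sample(which(labels))
    neg <- sample(which(!labels))
    out <- vector("list", n_subsets)
    ## deal positives forward and negatives backward so the size remainders
    ## of the two classes land on different subsets
    sub_pos <- rep_len(seq_len(n_subsets), length(pos))
    sub_neg <- rep_len(rev(seq_len(n_subsets)), length(neg))
    for (s in seq_len(n_subsets))
      out[[s]] <- sort(c(pos[sub_pos == s], neg[sub_neg == s]))
    out
  })
}

#' Information-gain ranking across balanced subsets (Ranker)
#'
#' Computes the information gain of every feature within each balanced
#' subset and reports the per-feature mean and standard deviation across
#' subsets, sorted by decreasing mean.
#'
#' @param data A [modeling_dataset()].
#' @param n_subsets Number of balanced subsets.
#' @param seed Integer seed for the subset assignment.
#' @return Data frame `feature`, `ranker_mean`, `ranker_sd`, sorted
#'   descending by mean gain.
#' @export
ranker_evaluate <- function(data, n_subsets = 100L, seed = 1L) {
  stopifnot(inherits(data, "modeling_dataset"))
  subsets <- make_balanced_subsets(data$labels, n_subsets, seed)
  gains <- sapply(data$feature_names, function(f)
    vapply(subsets, function(idx)
      information_gain(data$features[idx, f], data$labels[idx]),
      numeric(1)))
  out <- data.frame(feature = data$feature_names,
                    ranker_mean = colMeans(gains),
                    ranker_sd = apply(gains, 2L, sd),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$ranker_mean, out$feature), , drop = FALSE]
}

#' Wrapper feature selection across balanced subsets (WrapperEval)
#'
#' For each of the `n_subsets` iterations, one subset is held out and a
#' decision-tree learner is evaluated on it while trained on the remaining
#' subsets. In `"forward"` mode (default) greedy forward selection adds, at
#' each round, the feature whose addition most improves held-out accuracy,
#' stopping when no addition improves it; a feature's score is the number of
#' iterations in which it was selected. In `"removal"` mode the tree is
#' trained on all features and a feature scores an iteration when removing
#' it lowers held-out accuracy.
#'
#' @param data A [modeling_dataset()].
#' @param n_subsets Number of balanced subsets (= iterations).
#' @param seed Integer seed for the subset assignment.
#' @param mode `"forward"` or `"removal"`.
#' @param max_depth Depth of the decision-tree learner.
#' @return Data frame `feature`, `wrapper_count` (0..`n_subsets`), sorted
#'   descending by count.
#' @export
wrapper_evaluate <- function(data, n_subsets = 100L, seed = 1L,
                             mode = c("forward", "removal"),
                             max_depth = 2L) {
  stopifnot(inherits(data, "modeling_dataset"))
  mode <- match.arg(mode)
  subsets <- make_balanced_subsets(data$labels, n_subsets, seed)
  feats <- data$feature_names
  counts <- setNames(integer(length(feats)), feats)
  acc <- function(train_idx, test_idx, fset) {
    fit <- train_decision_tree(md_subset(data, train_idx), fset, max_depth)
    pred <- predict(fit, data$features[test_idx, fset, drop = FALSE])
    mean(pred == data$labels[test_idx])
  }
  for (i in seq_along(subsets)) {
    test_idx <- subsets[[i]]
    train_idx <- setdiff(seq_along(data$labels), test_idx)
    if (mode == "forward") {
      selected <- character()
      best <- max(mean(data$labels[test_idx]),
                  1 - mean(data$labels[test_idx]))   # majority-class baseline
      repeat {
        remaining <- setdiff(feats, selected)
        if (!length(remaining)) break
        trial <- vapply(remaining, function(f)
          acc(train_idx, test_idx, c(selected, f)), numeric(1))
        if (max(trial) > best + 1e-12) {
          pick <- remaining[which.max(trial)]
          selected <- c(selected, pick)
          best <- max(trial)
        } else break
      }
      counts[selected] <- counts[selected] + 1L
    } else {
      full <- acc(train_idx, test_idx, feats)
      for (f in feats)
        if (length(feats) > 1L &&
            acc(train_idx, test_idx, setdiff(feats, f)) < full - 1e-12)
          counts[f] <- counts[f] + 1L
    }
  }
  out <- data.frame(feature = feats, wrapper_count = unname(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$wrapper_count, out$feature), , drop = FALSE]
}

#' Combined importance report
#'
#' Runs [ranker_evaluate()] and [wrapper_evaluate()] on the same subset
#' assignment and merges them into one table mirroring the conventional
#' report layout (mean gain, gain SD, wrapper selection frequency).
#'
#' @inheritParams wrapper_evaluate
#' @return Data frame `feature`, `ranker_mean`, `ranker_sd`,
#'   `wrapper_count`, sorted descending by mean gain.
#' @export
importance_report <- function(data, n_subsets = 100L, seed = 1L,
                              mode = "forward", max_depth = 2L) {
  r <- ranker_evaluate(data, n_subsets, seed)
  w <- wrapper_evaluate(data, n_subsets, seed, mode, max_depth)
  out <- merge(r, w, by = "feature", sort = FALSE)
  out[order(-out$ranker_mean, out$feature), , drop = FALSE]
}

#' @rdname importance_report
#' @param report An importance report data frame.
#' @param path Output TSV path.
#' @export
write_importance_report <- function(report, path) {
  write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
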