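## Similarity-constrained k-nearest-neighbour toxicant classifier: a
## substance is predicted toxic when the majority of its k most similar
## neighbours above the similarity threshold are toxic. Its per-substance
## prediction doubles as a feature for the supervised learners.

#' KNN classifier configuration
#'
#' Defaults follow the conventional read-across setting: the 5 closest
#' neighbours vote, and a substance only counts as a neighbour when its
#' Tanimoto similarity is at least 0.7. When fewer than `k` candidates exist
#' the available ones vote; an even split falls back to `tie_rule`
#' (non-toxicant by default, the majority class of typical dossier data).
#' With no candidate at all the prediction is the `tie_rule` default and the
#' query is flagged out of the applicability domain. Ties in similarity at
#' the k-th rank are broken by ascending substance id for determinism.
#'
#' @param k Number of voting neighbours.
#' @param neighbor_threshold Minimum Tanimoto similarity for neighbourhood.
#' @param tie_rule `"predict_negative"` or `"predict_positive"`.
#' @param self_exclusion Exclude the query substance from its own neighbour
#'   list (always advisable: the query's own label would leak).
#' @return A `knn_config` list.
#' @export
knn_config <- function(k = 5L, neighbor_threshold = 0.7,
                       tie_rule = c("predict_negative", "predict_positive"),
                       self_exclusion = TRUE) {
  tie_rule <- match.arg(tie_rule)
  stopifnot(k >= 1L, neighbor_threshold >= 0, neighbor_threshold <= 1)
  structure(list(k = as.integer(k), neighbor_threshold = neighbor_threshold,
                 tie_rule = tie_rule, self_exclusion = isTRUE(self_exclusion)),
            class = "knn_config")
}

## Internal: vote given candidate similarities/labels/ids already above the
## threshold. Returns list(prediction, n_neighbors_used, in_domain).
knn_vote <- function(sims, labels, ids, cfg) {
  if (length(sims) == 0L)
    return(list(prediction = cfg$tie_rule == "predict_positive",
                n_neighbors_used = 0L, in_domain = FALSE))
  ord <- order(-sims, ids)                 # most similar first, id tie-break
  top <- ord[seq_len(min(cfg$k, length(ord)))]
  pos <- sum(labels[top]); n <- length(top)
  pred <- if (2L * pos > n) TRUE
          else if (2L * pos < n) FALSE
          else cfg$tie_rule == "predict_positive"
  list(prediction = pred, n_neighbors_used = n, in_domain = TRUE)
}

#' Predict toxicity of one substance by thresholded KNN
#'
#' Candidate neighbours are the reference substances whose Tanimoto
#' similarity to the query is at least `neighbor_threshold` (the query itself
#' is excluded under `self_exclusion`); the `k` most similar candidates vote
#' and the majority wins. `in_domain` is `TRUE` when at least one candidate
#' neighbour exists.
#'
#' @param query Logical fingerprint vector (or 1-row matrix) of the query.
#' @param ref_fp Fingerprint matrix of the reference set, ids as rownames.
#' @param ref_labels Logical toxicant labels aligned with `ref_fp` rows.
#' @param cfg A [knn_config()].
#' @param query_id Optional id of the query, used for self-exclusion when the
#'   query is part of the reference set.
#' @return List with `prediction` (logical), `n_neighbors_used`, `in_domain`.
#' @export
knn_predict <- function(query, ref_fp, ref_labels, cfg = knn_config(),
                        query_id = NULL) {
  ref_fp <- as.matrix(ref_fp)
  if (nrow(ref_fp) == 0L) stop("empty reference set", call. = FALSE)
  query <- as.logical(query)
  if (length(query) != ncol(ref_fp))
    stop("fingerprint length mismatch between query and reference",
         call. = FALSE)
  stopifnot(length(ref_labels) == nrow(ref_fp))
  ids <- rownames(ref_fp)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ref_fp)))
  keep <- rep(TRUE, nrow(ref_fp))
  if (cfg$self_exclusion && !is.null(query_id)) keep <- ids != query_id
  sims <- vapply(which(keep), function(i) {
    u <- sum(query | ref_fp[i, ])
    if (u == 0L) return(NA_real_)          # both empty: similarity undefined
    sum(query & ref_fp[i, ]) / u
  }, numeric(1))
  ok <- !is.na(sims) & sims >= cfg$neighbor_threshold
  knn_vote(sims[ok], as.logical(ref_labels)[which(keep)][ok],
           ids[keep][ok], cfg)
}

#' Leave-self-out KNN predictions for a whole dataset
#'
#' Computes, for every substance, the KNN prediction against all other
#' substances in the set. The resulting 0/1 column is both the standalone
#' KNN evaluation and the similarity feature fused into the supervised
#' learners.
#'
#' @param fp Fingerprint matrix, substance ids as rownames.
#' @param labels Logical toxicant labels aligned with rows.
#' @param cfg A [knn_config()].
#' @param sim Optional precomputed similarity matrix from
#'   [tanimoto_matrix()] (saves the dominant cost when called repeatedly).
#' @return Data frame `substance_id`, `knn_prediction` (0/1), `n_neighbors`,
#'   `in_domain`, in input row order.
#' @export
knn_feature_column <- function(fp, labels, cfg = knn_config(), sim = NULL) {
  fp <- as.matrix(fp)
  n <- nrow(fp)
  stopifnot(length(labels) == n)
  ids <- rownames(fp)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(sim)) sim <- tanimoto_matrix(fp)
  labels <- as.logical(labels)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sim[i, ]
    cand <- which(!is.na(s) & s >= cfg$neighbor_threshold)
    if (cfg$self_exclusion) cand <- setdiff(cand, i)
    out[[i]] <- knn_vote(s[cand], labels[cand], ids[cand], cfg)
  }
  data.frame(substance_id = ids,
             knn_prediction = as.integer(vapply(out, `[[`, logical(1),
                                                "prediction")),
             n_neighbors = vapply(out, `[[`, integer(1), "n_neighbors_used"),
             in_domain = vapply(out, `[[`, logical(1), "in_domain"),
             stringsAsFactors = FALSE)
}

#' KNN predictions for new substances against a labelled reference set
#'
#' Used inside cross-validation: each held-out substance is predicted from
#' the training fold only, so the similarity feature never sees the held-out
#' labels.
#'
#' @param query_fp Fingerprint matrix of query substances.
#' @param ref_fp,ref_labels Labelled reference fingerprints.
#' @param cfg A [knn_config()].
#' @return Data frame as in [knn_feature_column()].
#' @export
knn_predict_matrix <- function(query_fp, ref_fp, ref_labels,
                               cfg = knn_config()) {
  query_fp <- as.matrix(query_fp); ref_fp <- as.matrix(ref_fp)
  if (ncol(query_fp) != ncol(ref_fp))
    stop("fingerprint length mismatch between query and reference",
         call. = FALSE)
  qids <- rownames(query_fp)
  if (is.null(qids)) qids <- as.character(seq_len(nrow(query_fp)))
  out <- vector("list", nrow(query_fp))
  for (i in seq_len(nrow(query_fp)))
    out[[i]] <- knn_predict(query_fp[i, ], ref_fp, ref_labels, cfg,
                            query_id = qids[i])
  data.frame(substance_id = qids,
             knn_prediction = as.integer(vapply(out, `[[`, logical(1),
                                                "prediction")),
             n_neighbors = vapply(out, `[[`, integer(1), "n_neighbors_used"),
             in_domain = vapply(out, `[[`, logical(1), "in_domain"),
             stringsAsFactors = FALSE)
}
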