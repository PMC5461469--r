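## Brute-force oracles and small fixture builders shared across tests.

## Explicit-scan KNN oracle: full pairwise similarity, threshold filter,
## stable sort by (-similarity, id), majority vote over the top k.
oracle_knn <- function(i, fp, labels, cfg) {
  ids <- rownames(fp)
  sims <- rep(NA_real_, nrow(fp))
  for (j in seq_len(nrow(fp))) {
    if (cfg$self_exclusion && j == i) next
    u <- sum(fp[i, ] | fp[j, ])
    if (u == 0) next
    sims[j] <- sum(fp[i, ] & fp[j, ]) / u
  }
  cand <- which(!is.na(sims) & sims >= cfg$neighbor_threshold)
  if (!length(cand))
    return(list(prediction = cfg$tie_rule == "predict_positive",
                n_neighbors_used = 0L, in_domain = FALSE))
  ord <- cand[order(-sims[cand], ids[cand])]
  top <- ord[seq_len(min(cfg$k, length(ord)))]
  pos <- sum(labels[top])
  pred <- if (2 * pos > length(top)) TRUE
          else if (2 * pos < length(top)) FALSE
          else cfg$tie_rule == "predict_positive"
  list(prediction = pred, n_neighbors_used = length(top), in_domain = TRUE)
}

## Enumerate all set partitions of 1..n as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  grow <- function(rgs, maxv) {
    k <- length(rgs)
    if (k == n) { out[[length(out) + 1L]] <<- rgs; return(invisible()) }
    for (v in 0:(maxv + 1L)) grow(c(rgs, v), max(maxv, v))
  }
  grow(0L, 0L)
  out
}

## Modularity of a membership vector on an adjacency matrix (independent of
## the package implementation).
oracle_q <- function(adj, memb) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (c in unique(memb)) {
    idx <- which(memb == c)
    e_c <- sum(adj[idx, idx, drop = FALSE]) / 2
    d_c <- sum(deg[idx])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

## Exhaustive-search optimal modularity over all partitions (n <= 8).
oracle_best_q <- function(adj) {
  n <- nrow(adj)
  best <- -Inf
  for (p in all_partitions(n)) best <- max(best, oracle_q(adj, p))
  best
}

## Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

## Fingerprint matrix from a list of on-bit index vectors.
fp_from_bits <- function(bit_sets, n_bits, ids = NULL) {
  m <- matrix(FALSE, length(bit_sets), n_bits)
  for (i in seq_along(bit_sets)) m[i, bit_sets[[i]]] <- TRUE
  rownames(m) <- if (is.null(ids)) sprintf("S%03d", seq_along(bit_sets)) else ids
  m
}

## Minimal well-formed study table.
make_studies <- function(values, substance_id = "S1", endpoint = "acute_oral",
                         guideline = "TG401", klimisch = 1L,
                         key_study = TRUE, read_across = FALSE,
                         qualifier = "exact") {
  as_study_table(data.frame(
    substance_id = substance_id, endpoint = endpoint, guideline = guideline,
    klimisch = klimisch, key_study = key_study, read_across = read_across,
    value = values, qualifier = qualifier, stringsAsFactors = FALSE))
}

## A trivial majority-class learner with a predict method, for exercising
## the evaluation protocols without model cost.
majority_learner <- function(train) {
  structure(list(pred = mean(train$labels) >= 0.5), class = "const_model")
}
predict.const_model <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata)) nrow(newdata) else nrow(newdata$features)
  rep(object$pred, n)
}
registerS3method("predict", "const_model", predict.const_model,
                 envir = asNamespace("stats"))

## Hazard table with given per-hazard status counts.
make_hazards <- function(counts) {
  n <- max(vapply(counts, sum, numeric(1)))
  df <- data.frame(substance_id = sprintf("S%05d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (h in names(counts)) {
    cc <- counts[[h]]
    df[[h]] <- c(rep(c("positive", "negative", "data_lacking",
                       "inconclusive"), cc),
                 rep("data_lacking", n - sum(cc)))
  }
  df
}
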