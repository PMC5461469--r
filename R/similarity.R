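## Tanimoto similarity, thresholded similarity graph, and modularity-based
## module detection. Module membership delimits the applicability domains
## over which the classifiers are evaluated.

#' Tanimoto similarity between two binary fingerprints
#'
#' The number of shared on-bits divided by the number of bits on in either
#' fingerprint, \eqn{|A \cap B| / |A \cup B|}. Undefined when both
#' fingerprints are empty; that case is an error, not silently zero.
#'
#' @param a,b Logical (or 0/1) vectors of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("fingerprints have different lengths", call. = FALSE)
  u <- sum(a | b)
  if (u == 0L)
    stop("Tanimoto similarity is undefined for two empty fingerprints",
         call. = FALSE)
  sum(a & b) / u
}

#' All-pairs Tanimoto similarity matrix
#'
#' Computed by bit-count cross products; rows/columns follow the fingerprint
#' matrix. Pairs where both fingerprints are empty get `NA`.
#'
#' @param fp Logical (or 0/1) matrix, substances in rows.
#' @return Symmetric numeric matrix with unit diagonal (where defined).
#' @export
tanimoto_matrix <- function(fp) {
  m <- matrix(as.numeric(as.matrix(fp) != 0), nrow = nrow(fp),
              dimnames = dimnames(fp))
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  union <- outer(ones, ones, "+") - inter
  s <- inter / union                 # 0/0 -> NaN for empty-empty pairs
  s[union == 0] <- NA_real_
  s
}

#' Build a thresholded similarity graph
#'
#' Nodes are substances; an undirected edge connects every pair whose
#' Tanimoto similarity is at or above the threshold (default 0.7, the
#' conventional read-across neighbourhood). Similarity weights are stored on
#' the edges for nearest-neighbour use, but module detection treats the graph
#' as unweighted.
#'
#' @param fp Fingerprint matrix with substance ids as rownames (>= 2 rows).
#' @param threshold Minimum similarity for an edge, in `[0, 1]`.
#' @return A `similarity_graph`: list with `graph` (igraph), `threshold`,
#'   and `module_of` (`NA` until [detect_modules()] is run).
#' @export
build_graph <- function(fp, threshold = 0.7) {
  fp <- as.matrix(fp)
  if (nrow(fp) < 2L) stop("need at least 2 substances", call. = FALSE)
  ids <- rownames(fp)
  if (is.null(ids)) stop("fingerprint matrix needs rownames", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate substance ids", call. = FALSE)
  s <- tanimoto_matrix(fp)
  s[is.na(s)] <- -Inf               # undefined pairs can never reach threshold
  keep <- which(upper.tri(s) & s >= threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(fp), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(keep)) {
    g <- igraph::add_edges(g, rbind(keep[, 1L], keep[, 2L]))
    g <- igraph::set_edge_attr(g, "similarity", value = s[keep])
  }
  structure(list(graph = g, threshold = threshold,
                 module_of = setNames(rep(NA_integer_, length(ids)), ids),
                 q = NA_real_),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d substances, %d edges at threshold %.2f\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  if (!anyNA(x$module_of))
    cat(sprintf("  %d modules, Q = %.4f\n", length(unique(x$module_of)), x$q))
  invisible(x)
}

#' Detect chemical modules by modularity maximisation
#'
#' Maximises Newman--Girvan modularity on the unweighted thresholded graph
#' at resolution 1. At realistic scale this is greedy multi-level
#' (Louvain-style) optimisation with several perturbed-order restarts,
#' keeping the best-Q partition; graphs at or below `exact_below` nodes are
#' instead solved exactly by integer programming
#' ([igraph::cluster_optimal()]), since greedy aggregation can lodge in
#' local optima that only coordinated multi-node moves escape. Results are
#' deterministic under `seed`. Isolated substances become singleton
#' modules. Module ids are contiguous integers from 0, numbered by
#' decreasing module size (ties by smallest member id).
#'
#' @param sg A `similarity_graph` from [build_graph()].
#' @param seed Integer seed controlling the node-visit order.
#' @param n_restarts Number of perturbed Louvain restarts.
#' @param exact_below Node count at or below which the exact optimiser is
#'   used.
#' @return The graph with `module_of` filled and `q` set to the modularity of
#'   the returned partition.
#' @export
detect_modules <- function(sg, seed = 1L, n_restarts = 8L,
                           exact_below = 12L) {
  stopifnot(inherits(sg, "similarity_graph"))
  g <- sg$graph
  ids <- igraph::V(g)$name
  if (igraph::ecount(g) == 0L) {
    warning("graph has no edges: every substance is its own module")
    sg$module_of <- setNames(seq_along(ids) - 1L, ids)
    sg$q <- 0
    return(sg)
  }
  gu <- if ("similarity" %in% igraph::edge_attr_names(g))
    igraph::delete_edge_attr(g, "similarity") else g
  if (igraph::vcount(gu) <= exact_below) {
    memb <- igraph::membership(igraph::cluster_optimal(gu))
    return(finish_modules(sg, gu, memb, ids))
  }
  best <- NULL; best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    memb <- with_seed(derive_seed(seed, paste0("louvain", r)), {
      perm <- sample.int(igraph::vcount(gu))
      gp <- igraph::permute(gu, perm)
      cl <- igraph::cluster_louvain(gp, resolution = 1)
      m <- igraph::membership(cl)
      m[match(igraph::V(gu)$name, igraph::V(gp)$name)]
    })
    q <- modularity_q_membership(gu, memb)
    if (q > best_q + 1e-12) { best_q <- q; best <- memb }
  }
  finish_modules(sg, gu, best, ids)
}

## Renumber a membership vector 0-based by decreasing module size (ties by
## smallest member index) and attach it with its Q.
finish_modules <- function(sg, gu, memb, ids) {
  sizes <- table(memb)
  first <- tapply(seq_along(memb), memb, min)
  ord <- order(-as.integer(sizes), as.integer(first))
  remap <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  sg$module_of <- setNames(as.integer(remap[as.character(memb)]), ids)
  sg$q <- modularity_q_membership(gu, memb)
  sg
}

#' Newman--Girvan modularity of a partition
#'
#' \eqn{Q = \sum_c [e_c/m - (d_c/2m)^2]} over modules c, where `e_c` is the
#' number of intra-module edges, `d_c` the total degree of the module and `m`
#' the edge count, on the unweighted thresholded graph.
#'
#' @param sg A `similarity_graph` (or igraph).
#' @param partition Named vector mapping every node id to a module label.
#' @return Modularity Q (0 for an edgeless graph, by convention).
#' @export
modularity_q <- function(sg, partition) {
  g <- if (inherits(sg, "similarity_graph")) sg$graph else sg
  ids <- igraph::V(g)$name
  if (!all(ids %in% names(partition)))
    stop("partition is missing node(s): ",
         paste(head(setdiff(ids, names(partition)), 5L), collapse = ", "),
         call. = FALSE)
  modularity_q_membership(g, partition[ids])
}

modularity_q_membership <- function(g, memb) {
  m <- igraph::ecount(g)
  if (m == 0L) return(0)
  memb <- as.character(memb)
  ends <- igraph::as_edgelist(g, names = FALSE)
  intra <- memb[ends[, 1L]] == memb[ends[, 2L]]
  e_c <- table(factor(memb[ends[, 1L]][intra], levels = unique(memb)))
  deg <- igraph::degree(g)
  d_c <- tapply(deg, factor(memb, levels = unique(memb)), sum)
  d_c[is.na(d_c)] <- 0
  sum(as.numeric(e_c) / m - (as.numeric(d_c) / (2 * m))^2)
}

#' Export a similarity graph to plain-text edge and module tables
#'
#' Writes an edge list TSV (`id_a`, `id_b`, `similarity`) and, when modules
#' have been assigned, a module TSV (`substance_id`, `module`).
#'
#' @param sg A `similarity_graph`.
#' @param edges_path,modules_path Output paths (`NULL` to skip one).
#' @return Invisibly, the paths written.
#' @export
write_graph_tables <- function(sg, edges_path = NULL, modules_path = NULL) {
  stopifnot(inherits(sg, "similarity_graph"))
  written <- character()
  if (!is.null(edges_path)) {
    el <- igraph::as_edgelist(sg$graph)
    sim <- igraph::E(sg$graph)$similarity
    df <- data.frame(id_a = el[, 1L], id_b = el[, 2L],
                     similarity = if (length(sim)) sim else numeric())
    write.table(df, edges_path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, edges_path)
  }
  if (!is.null(modules_path) && !anyNA(sg$module_of)) {
    df <- data.frame(substance_id = names(sg$module_of),
                     module = as.integer(sg$module_of))
    write.table(df, modules_path, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, modules_path)
  }
  invisible(written)
}
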