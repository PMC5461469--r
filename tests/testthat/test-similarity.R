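test_that("tanimoto matches set arithmetic and rejects the undefined case", {
  a <- fp_from_bits(list(c(1, 2, 3)), 8)[1, ]
  b <- fp_from_bits(list(c(2, 3, 4)), 8)[1, ]
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), 0.5)                 # |int| 2 / |union| 4
  expect_equal(tanimoto(a, fp_from_bits(list(c(5, 6)), 8)[1, ]), 0)
  expect_error(tanimoto(logical(8), logical(8)), "undefined")
  expect_error(tanimoto(a, logical(4)), "length")

  ## symmetry, and similarity 1 iff identical, over random nonempty pairs
  set.seed(42)
  for (i in 1:25) {
    x <- runif(32) < 0.4; y <- runif(32) < 0.4
    x[1] <- TRUE; y[2] <- TRUE
    expect_identical(tanimoto(x, y), tanimoto(y, x))
    expect_identical(tanimoto(x, y) == 1, identical(x, y))
  }
})

test_that("tanimoto_matrix agrees with pairwise computation", {
  set.seed(7)
  fp <- matrix(runif(10 * 24) < 0.3, 10)
  fp[, 1] <- TRUE
  rownames(fp) <- letters[1:10]
  s <- tanimoto_matrix(fp)
  for (i in 1:10) for (j in 1:10)
    expect_equal(s[i, j], tanimoto(fp[i, ], fp[j, ]))
})

test_that("build_graph keeps exactly the at-threshold pairs", {
  set.seed(11)
  fp <- matrix(runif(12 * 48) < 0.35, 12)
  fp[, 1] <- TRUE
  rownames(fp) <- sprintf("S%02d", 1:12)
  sg0 <- build_graph(fp, threshold = 0)
  expect_equal(igraph::ecount(sg0$graph), 12 * 11 / 2)   # complete graph
  expect_equal(igraph::ecount(build_graph(fp, threshold = 1.0001)$graph), 0L)

  thr <- 0.4
  sg <- build_graph(fp, thr)
  el <- igraph::as_edgelist(sg$graph)
  got <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  want <- character()
  for (i in 1:11) for (j in (i + 1):12)
    if (tanimoto(fp[i, ], fp[j, ]) >= thr)
      want <- c(want, paste(rownames(fp)[i], rownames(fp)[j]))
  expect_identical(got, sort(want))

  dup <- fp; rownames(dup) <- rep("X", 12)
  expect_error(build_graph(dup), "duplicate")
})

test_that("no between-module edges at 0.7 on well-separated synthetic data", {
  cfg <- generator_config(seed = 5, module_sizes = c(20L, 20L),
                          within_module_similarity = 0.9)
  g <- generate_fingerprints(cfg)
  sg <- build_graph(g$fingerprints, 0.7)
  el <- igraph::as_edgelist(sg$graph)
  mod <- setNames(g$substances$module, g$substances$substance_id)
  expect_true(all(mod[el[, 1]] == mod[el[, 2]]))
  ## oracle scan agrees that no cross pair reaches the threshold
  cross_max <- max(tanimoto_matrix(g$fingerprints)[
    g$substances$module == 0, g$substances$module == 1])
  expect_lt(cross_max, 0.7)
})

test_that("modularity_q matches closed forms and the igraph reference", {
  ## two disjoint 4-cliques, partitioned as the cliques: Q = 0.5
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1; adj[5:8, 5:8] <- 1; diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
  igraph::V(g)$name <- letters[1:8]
  part <- setNames(rep(c(0, 1), each = 4), letters[1:8])
  expect_equal(modularity_q(g, part), 0.5)
  expect_equal(modularity_q(g, setNames(rep(0, 8), letters[1:8])), 0)
  expect_error(modularity_q(g, part[1:5]), "missing node")

  ## independent reference on random graphs
  set.seed(3)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    rg <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(rg) == 0) next
    igraph::V(rg)$name <- paste0("n", seq_len(n))
    memb <- sample(0:2, n, replace = TRUE)
    q <- modularity_q(rg, setNames(memb, paste0("n", seq_len(n))))
    expect_equal(q, igraph::modularity(rg, memb + 1L))
    expect_gte(q, -0.5); expect_lt(q, 1)
  }
})

test_that("module detection solves small graphs exactly", {
  ## two triangles joined by a bridge: optimum is the two triangles
  fp <- fp_from_bits(list(1:8, 1:8, 1:8, 9:16, 9:16, 9:16), 16)
  sg <- build_graph(fp, threshold = 0.9)
  bridge <- igraph::add_edges(sg$graph, c(3, 4))
  sg$graph <- bridge
  sg <- detect_modules(sg)
  m <- unname(sg$module_of)
  expect_length(unique(m), 2L)
  expect_length(unique(m[1:3]), 1L)           # first triangle together
  expect_length(unique(m[4:6]), 1L)           # second triangle together
  expect_false(m[1] == m[4])
  adj <- as.matrix(igraph::as_adjacency_matrix(bridge))
  expect_equal(sg$q, oracle_best_q(adj), tolerance = 1e-9)

  ## complete graph: one module, Q = 0
  cg <- build_graph(fp_from_bits(rep(list(1:8), 5), 16), 0.5)
  cg <- detect_modules(cg)
  expect_length(unique(cg$module_of), 1L)
  expect_equal(cg$q, 0)

  ## edgeless graph: singletons with a warning
  iso <- build_graph(fp_from_bits(list(1:4, 9:12, 13:16), 16), 0.9)
  expect_warning(iso <- detect_modules(iso), "no edges")
  expect_equal(sort(unname(iso$module_of)), 0:2)
  expect_equal(iso$q, 0)
})

test_that("detected modularity equals the exhaustive optimum on small graphs", {
  set.seed(19)
  n_checked <- 0
  for (trial in 1:50) {
    n <- sample(4:8, 1)
    adj <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- as.numeric(runif(1) < 0.45)
    if (sum(adj) == 0) next
    g <- igraph::graph_from_adjacency_matrix(adj, "undirected")
    igraph::V(g)$name <- paste0("n", seq_len(n))
    sg <- structure(list(graph = g, threshold = NA_real_,
                         module_of = setNames(rep(NA_integer_, n),
                                              paste0("n", seq_len(n))),
                         q = NA_real_), class = "similarity_graph")
    sg <- suppressWarnings(detect_modules(sg, seed = trial))
    best <- oracle_best_q(adj)
    expect_lte(sg$q, best + 1e-9)
    expect_equal(sg$q, best, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 40)
})

test_that("nine planted modules are recovered on separated synthetic data", {
  cfg <- generator_config(seed = 21, module_sizes = rep(30L, 9),
                          within_module_similarity = 0.9)
  g <- generate_fingerprints(cfg)
  sg <- detect_modules(build_graph(g$fingerprints, 0.7), seed = 1)
  found <- sg$module_of[g$substances$substance_id]
  expect_equal(length(unique(found)), 9L)
  expect_gt(adjusted_rand(g$substances$module, found), 0.9)
  ## detected Q beats the trivial partitions
  ids <- g$substances$substance_id
  expect_gte(sg$q, modularity_q(sg, setNames(seq_along(ids), ids)))
  expect_gte(sg$q, modularity_q(sg, setNames(rep(0, length(ids)), ids)))
})

test_that("graph export writes loadable edge and module tables", {
  cfg <- generator_config(seed = 2, module_sizes = c(10L, 10L))
  g <- generate_fingerprints(cfg)
  sg <- detect_modules(build_graph(g$fingerprints, 0.7), seed = 1)
  e_path <- withr::local_tempfile(fileext = ".tsv")
  m_path <- withr::local_tempfile(fileext = ".tsv")
  write_graph_tables(sg, e_path, m_path)
  edges <- read.table(e_path, header = TRUE, sep = "\t")
  expect_equal(nrow(edges), igraph::ecount(sg$graph))
  expect_true(all(edges$similarity >= 0.7))
  mods <- read.table(m_path, header = TRUE, sep = "\t")
  expect_equal(nrow(mods), 20L)
})
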