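test_that("newick parsing validates and round-trips", {
  t1 <- parse_newick("(A:1,B:2);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  expect_setequal(t1$edge.length, c(1, 2))
  expect_setequal(parse_newick("((A:1,B:1):1,C:2);")$tip.label, c("A", "B", "C"))
  expect_error(parse_newick("((A:1,B:2);"), "unbalanced")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
  expect_warning(parse_newick("(A,B:2);"), "branch lengths")
  cfg <- simulation_config(n_leaves = 50, seed = 3)
  tr <- random_binary_tree(cfg)
  tr2 <- parse_newick(write_newick(tr))
  expect_equal(rf_distance(tr, tr2), 0, ignore_attr = TRUE)
  expect_equal(leaf_distance_matrix(tr2)[tr$tip.label, tr$tip.label],
               leaf_distance_matrix(tr)[tr$tip.label, tr$tip.label],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("leaf distance matrix equals brute-force path sums", {
  tree <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);")
  D <- leaf_distance_matrix(tree)
  expect_equal(D["A", "B"], 3)
  expect_equal(D["C", "D"], 2)
  expect_equal(D["A", "C"], 5)
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  expect_equal(D, t(D))
  cfg <- simulation_config(n_leaves = 12, seed = 17)
  tr <- random_binary_tree(cfg)
  Dr <- leaf_distance_matrix(tr)
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    a <- tr$tip.label[pair[1]]; b <- tr$tip.label[pair[2]]
    expect_equal(Dr[a, b], bruteforce_leaf_distance(tr, a, b),
                 tolerance = 1e-12)
  }
})

test_that("tree distances satisfy the four-point condition", {
  cfg <- simulation_config(n_leaves = 10, seed = 19)
  tr <- random_binary_tree(cfg)
  D <- leaf_distance_matrix(tr)
  set.seed(19)
  for (k in 1:50) {
    q <- sample(nrow(D), 4)
    sums <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
                   D[q[1], q[3]] + D[q[2], q[4]],
                   D[q[1], q[4]] + D[q[2], q[3]]))
    expect_equal(sums[2], sums[3], tolerance = 1e-9)
  }
})

test_that("RF distance agrees with brute-force bipartition comparison", {
  t1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(rf_distance(t1, t1), 0, ignore_attr = TRUE)
  t2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(as.numeric(rf_distance(t1, t2)), 1)  # 4-leaf: single split differs
  set.seed(23)
  for (k in 1:10) {
    cfg <- simulation_config(n_leaves = 8, seed = 100 + k)
    tr <- random_binary_tree(cfg)
    tp <- perturb_gene_tree(tr, 1, seed = k)
    got <- rf_distance(tr, tp)
    expect_equal(attr(got, "raw"), bruteforce_rf(tr, tp))
    expect_equal(as.numeric(got), bruteforce_rf(tr, tp) / (2 * (8 - 3)))
  }
  expect_error(rf_distance(t1, parse_newick("((A:1,B:1):1,(C:1,E:1):1);")),
               "leaf label sets")
})

test_that("RF is a metric on random binary topologies", {
  trees <- lapply(1:3, function(k)
    random_binary_tree(simulation_config(n_leaves = 8, seed = 200 + k)))
  d <- function(a, b) as.numeric(rf_distance(trees[[a]], trees[[b]]))
  expect_equal(d(1, 1), 0)
  expect_equal(d(1, 2), d(2, 1))
  expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
})

test_that("sampled quartet distance matches exhaustive enumeration", {
  t1 <- caterpillar_tree(5)
  expect_equal(as.numeric(sampled_quartet_distance(t1, t1, 100)), 0)
  # shuffle leaves of a caterpillar: compare against direct enumeration
  t2 <- t1
  t2$tip.label <- c("t3", "t5", "t1", "t4", "t2")
  exact <- as.numeric(sampled_quartet_distance(t1, t2, exhaustive = TRUE))
  expect_equal(as.numeric(sampled_quartet_distance(t1, t2, n_samples = 5)),
               exact)  # C(5,4)=5 <= n_samples triggers the exhaustive path
  # Monte-Carlo on 20 leaves within 3 standard errors of the exhaustive value
  s1 <- random_binary_tree(simulation_config(n_leaves = 20, seed = 61))
  s2 <- perturb_gene_tree(s1, 8, seed = 61)
  exact20 <- as.numeric(sampled_quartet_distance(s1, s2, exhaustive = TRUE))
  n_mc <- 3000
  est <- as.numeric(sampled_quartet_distance(s1, s2, n_samples = n_mc, seed = 7))
  se <- sqrt(exact20 * (1 - exact20) / n_mc)
  expect_lt(abs(est - exact20), 3 * se + 1e-12)
  expect_equal(sampled_quartet_distance(s1, s2, n_samples = n_mc, seed = 7),
               sampled_quartet_distance(s1, s2, n_samples = n_mc, seed = 7))
})

test_that("random query splits prune without distorting surviving distances", {
  tree <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);")
  split <- random_query_split(tree, 0.25, seed = 2)
  expect_length(split$queries, 1)
  keep <- setdiff(tree$tip.label, split$queries)
  Dfull <- leaf_distance_matrix(tree)[keep, keep]
  Dback <- leaf_distance_matrix(split$backbone)[keep, keep]
  expect_equal(Dback, Dfull, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(random_query_split(tree, 0.25, seed = 2)$queries,
                   split$queries)
  big <- random_binary_tree(simulation_config(n_leaves = 200, seed = 71))
  expect_length(random_query_split(big, 0.05, seed = 1)$queries, 10)
})

test_that("clade-based query splits select disjoint clades of the right size", {
  tree <- balanced_tree(4)  # 16 leaves; clades of sizes 2, 4, 8
  s <- clade_query_split(tree, n_clades = 2, min_size = 4, max_size = 4, seed = 5)
  expect_length(s$clades, 2)
  expect_true(all(lengths(s$clades) == 4))
  expect_length(intersect(s$clades[[1]], s$clades[[2]]), 0)
  expect_setequal(s$queries, unlist(s$clades))
  expect_identical(clade_query_split(tree, 2, 4, 4, seed = 5)$queries, s$queries)
  expect_error(clade_query_split(tree, n_clades = 5, min_size = 8, max_size = 8),
               "2 disjoint eligible")
  # a tree with exactly one eligible clade yields exactly that clade
  t2 <- parse_newick("(((A:1,B:1):1,(C:1,(D:1,E:1):1):1):1,F:1);")
  expect_warning(
    s2 <- clade_query_split(t2, 1, min_size = 5, max_size = 10, seed = 1),
    "no backbone")
  expect_setequal(s2$clades[[1]], c("A", "B", "C", "D", "E"))
})

test_that("placement edge error counts unrooted edges to the true attachment", {
  # hand-built 6-leaf tree; prune F and place it everywhere
  tree <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  backbone <- ape::drop.tip(tree, "F")
  tab <- canonical_edges(backbone)
  # true attachment: F's sibling is E, so the edge whose child clade is {E}
  true_edge <- tab$edge_id[tab$is_terminal & tab$child_label == "E"]
  expect_equal(placement_edge_error(tree, backbone, "F", true_edge), 0)
  # independent BFS oracle on the unrooted line graph for every edge
  ub <- ape::unroot(backbone)
  utab <- canonical_edges(ub)
  adj <- matrix(FALSE, nrow(utab), nrow(utab))
  for (a in seq_len(nrow(utab))) for (b in seq_len(nrow(utab))) {
    adj[a, b] <- a != b &&
      length(intersect(c(utab$parent[a], utab$child[a]),
                       c(utab$parent[b], utab$child[b]))) > 0
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  key <- function(clade, labels) {
    sides <- list(sort(clade), sort(setdiff(labels, clade)))
    sides <- sides[order(vapply(sides, paste, "", collapse = "|"))]
    paste(sides[[1]], collapse = "|")
  }
  ukeys <- vapply(utab$clade, key, "", labels = backbone$tip.label)
  bkeys <- vapply(canonical_edges(backbone)$clade, key, "",
                  labels = backbone$tip.label)
  true_u <- match(bkeys[true_edge], ukeys)
  dists <- as.vector(igraph::distances(g, v = true_u))
  for (e in seq_len(nrow(tab))) {
    expect_equal(placement_edge_error(tree, backbone, "F", e),
                 dists[match(bkeys[e], ukeys)])
  }
})

test_that("pruning and re-grafting a leaf restores the distance matrix", {
  cfg <- simulation_config(n_leaves = 10, seed = 83)
  tr <- random_binary_tree(cfg)
  D0 <- leaf_distance_matrix(tr)
  q <- tr$tip.label[4]
  backbone <- ape::drop.tip(tr, q)
  # re-graft at the recorded position using the true distances
  tab <- true_distance_table(tr, backbone, q)
  pl <- place_query(backbone, tab, q, b = 5)
  regrafted <- attach_query(backbone, q, pl)
  D1 <- leaf_distance_matrix(regrafted)[rownames(D0), colnames(D0)]
  expect_equal(D1, D0, tolerance = 1e-9, ignore_attr = TRUE)
})
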