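test_that("query distance tables match brute-force scaled distances", {
  b <- tiny_bundle(n = 8, L = 40, seed = 51)
  m <- tiny_model(40, seed = 51)
  m$normalization_factor <- 1.7
  m$mode$scale <- 0.8
  split <- random_query_split(b$tree, 0.25, seed = 51)
  q_aln <- subset_alignment(b$aln, split$queries)
  b_aln <- subset_alignment(b$aln, split$backbone$tip.label)
  tab <- query_distances(m, b_aln, q_aln)
  expect_equal(rownames(tab), q_aln$ids)
  expect_equal(colnames(tab), b_aln$ids)
  Pb <- embed_sequences(m, b_aln); Pq <- embed_sequences(m, q_aln)
  for (q in q_aln$ids) for (bb in b_aln$ids[1:3]) {
    expect_equal(tab[q, bb],
                 1.7 * scaled_distance(Pq[q, ], Pb[bb, ], m$mode),
                 tolerance = 1e-10)
  }
  # query identical to a backbone sequence sits at distance zero
  q2 <- alignment(stats::setNames(b_aln$seqs[1], "copycat"))
  tab2 <- query_distances(m, b_aln, q2)
  expect_equal(tab2["copycat", b_aln$ids[1]], 0, tolerance = 1e-12)
})

test_that("nearest references sort by distance with lexicographic ties", {
  tab <- matrix(c(3, 1, 2, 1), nrow = 1,
                dimnames = list("q", c("d", "b", "a", "c")))
  class(tab) <- c("query_distance_table", class(tab))
  expect_equal(nearest_references(tab, "q", 1), "b")
  expect_equal(nearest_references(tab, "q", 2), c("b", "c"))  # tie 1: b < c
  expect_equal(nearest_references(tab, "q", 10), c("b", "c", "a", "d"))
  expect_error(nearest_references(tab, "nope", 1), "unknown query")
})

test_that("placement with exact additive distances recovers the true edge", {
  for (seed in 1:6) {
    cfg <- simulation_config(n_leaves = 10, seed = 300 + seed)
    tr <- random_binary_tree(cfg)
    q <- tr$tip.label[seed]
    backbone <- ape::drop.tip(tr, q)
    tab <- true_distance_table(tr, backbone, q)
    pl <- place_query(backbone, tab, q, b = 5)
    expect_equal(placement_edge_error(tr, backbone, q, pl$edge_id), 0)
    expect_lt(pl$residual, 1e-15)
  }
})

test_that("placement degrades gracefully under small multiplicative noise", {
  hits <- 0
  for (seed in 1:5) {
    cfg <- simulation_config(n_leaves = 10, seed = 400 + seed)
    tr <- random_binary_tree(cfg)
    q <- tr$tip.label[1]
    backbone <- ape::drop.tip(tr, q)
    tab <- true_distance_table(tr, backbone, q)
    noisy <- tab * matrix(stats::runif(length(tab), 0.99, 1.01), nrow(tab))
    class(noisy) <- class(tab)
    pl <- place_query(backbone, noisy, q, b = 5)
    err <- placement_edge_error(tr, backbone, q, pl$edge_id)
    hits <- hits + (err <= 1)
  }
  expect_gte(hits, 3)  # majority of seeds at most one edge off
})

test_that("a query indistinguishable from a leaf lands on its terminal edge", {
  cfg <- simulation_config(n_leaves = 8, seed = 55)
  tr <- random_binary_tree(cfg)
  backbone <- ape::drop.tip(tr, tr$tip.label[1])
  leaf <- backbone$tip.label[3]
  tab <- matrix(leaf_distance_matrix(backbone)[leaf, ], nrow = 1,
                dimnames = list("q", backbone$tip.label))
  class(tab) <- c("query_distance_table", class(tab))
  pl <- place_query(backbone, tab, "q", b = 5)
  etab <- canonical_edges(backbone)
  expect_true(etab$is_terminal[pl$edge_id])
  expect_equal(etab$child_label[pl$edge_id], leaf)
  expect_equal(pl$pendant, 0)
})

test_that("update matrices keep the backbone block exact", {
  b <- tiny_bundle(n = 9, L = 40, seed = 61)
  split <- random_query_split(b$tree, 0.25, seed = 61)
  backbone <- split$backbone
  Db <- leaf_distance_matrix(backbone)
  # no queries: exactly the backbone distance matrix
  empty <- matrix(numeric(0), nrow = 0, ncol = ncol(Db),
                  dimnames = list(NULL, colnames(Db)))
  U0 <- build_update_matrix(backbone, empty)
  expect_equal(unclass(U0), unclass(Db), ignore_attr = TRUE)
  m <- train_embedding(tiny_model(40, seed = 61),
                       subset_alignment(b$aln, backbone$tip.label),
                       backbone, training_config(epochs = 3, seed = 61))
  q_aln <- subset_alignment(b$aln, split$queries)
  b_aln <- subset_alignment(b$aln, backbone$tip.label)
  tab <- query_distances(m, b_aln, q_aln)
  qq <- query_query_distances(m, q_aln)
  U <- build_update_matrix(backbone, tab, qq)
  bb <- backbone$tip.label
  expect_identical(U[bb, bb], unclass(Db)[bb, bb])
  expect_equal(U, t(U))
  expect_equal(diag(U), rep(0, nrow(U)), ignore_attr = TRUE)
  expect_equal(U[split$queries, bb], unclass(tab)[split$queries, bb])
  # single query: one new row/column, backbone block untouched
  one <- tab[1, , drop = FALSE]
  U1 <- build_update_matrix(backbone, one)
  expect_equal(nrow(U1), length(bb) + 1)
  expect_identical(U1[bb, bb], unclass(Db)[bb, bb])
  # the backbone block survives a file round trip bit-exactly
  path <- withr::local_tempfile(fileext = ".phylip")
  write_phylip_matrix(U, path)
  R <- read_phylip_matrix(path)
  expect_equal(R[bb, bb], U[bb, bb], tolerance = 1e-9)
})

test_that("gene matrices merge by the entrywise lower median", {
  m1 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- m1; m2[1, 2] <- m2[2, 1] <- 2
  m3 <- m1; m3[1, 2] <- m3[2, 1] <- 9
  expect_equal(merge_gene_matrices(list(m1)), m1)
  expect_equal(merge_gene_matrices(list(m1, m2, m3))[1, 2], 2)
  expect_equal(merge_gene_matrices(list(m3, m1, m2)),
               merge_gene_matrices(list(m1, m2, m3)))  # permutation-invariant
  expect_equal(merge_gene_matrices(list(m2, m2, m2)), m2)
  expect_equal(merge_gene_matrices(list(m1, m2))[1, 2], 1)  # lower median
  expect_error(merge_gene_matrices(list(m1, m1[1, 1, drop = FALSE])), "share")
})

test_that("PHYLIP matrices round-trip and reads validate the header", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  path <- withr::local_tempfile(fileext = ".phylip")
  write_phylip_matrix(m, path)
  expect_equal(read_phylip_matrix(path), m)
  lines <- readLines(path)
  expect_equal(lines[1], "3")
  expect_length(strsplit(trimws(lines[2]), "\\s+")[[1]], 4)
  writeLines(c("4", lines[-1]), path)
  expect_error(read_phylip_matrix(path), "header says 4")
  m2 <- m; rownames(m2)[1] <- "has space"
  expect_error(write_phylip_matrix(m2, path), "whitespace")
  # precision: 10 significant digits survive
  m3 <- m; m3[1, 2] <- m3[2, 1] <- 0.1234567891234
  write_phylip_matrix(m3, path)
  expect_equal(read_phylip_matrix(path)[1, 2], m3[1, 2], tolerance = 1e-9)
})
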