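test_that("tree-distance normalization divides by the maximum and round-trips", {
  tree <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);")
  D <- leaf_distance_matrix(tree)
  Dn <- normalize_tree_distances(D)
  expect_equal(max(Dn), 1)
  expect_equal(attr(Dn, "normalization_factor"), max(D))
  expect_equal(Dn * attr(Dn, "normalization_factor"), D,
               ignore_attr = TRUE)
  D1 <- D / max(D)
  attr(D1, "normalization_factor") <- 1
  Dn1 <- normalize_tree_distances(D1)
  expect_equal(unclass(Dn1), unclass(D1), ignore_attr = TRUE)
  expect_equal(attr(Dn1, "normalization_factor"), 1)
  Z <- matrix(0, 2, 2)
  expect_error(normalize_tree_distances(Z), "zero")
})

test_that("terminal pseudo-counts add exactly 2*eps to every leaf pair", {
  cfg <- simulation_config(n_leaves = 10, seed = 21)
  tree <- random_binary_tree(cfg)
  expect_identical(add_terminal_pseudocounts(tree, 0), tree)
  for (eps in c(1e-3, 1e-4)) {
    t2 <- add_terminal_pseudocounts(tree, eps)
    D1 <- leaf_distance_matrix(tree); D2 <- leaf_distance_matrix(t2)
    off <- upper.tri(D1)
    expect_equal(D2[off] - D1[off], rep(2 * eps, sum(off)))
    # brute-force recomputation of a few path lengths from scratch
    labs <- tree$tip.label[1:3]
    for (a in labs[1]) for (b in labs[-1]) {
      expect_equal(D2[a, b], bruteforce_leaf_distance(t2, a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted cost matches its definition on simple ratio patterns", {
  mode <- geometry_mode("loid", dim = 2)
  P <- rbind(loid_exp(c(0.4, 0)), loid_exp(c(-0.4, 0)), loid_exp(c(0, 0.9)))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  d <- apply(pairs, 1, function(p) loid_distance(P[p[1], ], P[p[2], ]))
  Dt <- matrix(0, 3, 3)
  Dt[pairs] <- d; Dt[pairs[, 2:1]] <- d
  expect_equal(weighted_cost(P, 1, Dt, pairs, mode), 0)
  Dt2 <- Dt / 2   # s*d = 2*dT everywhere
  expect_equal(weighted_cost(P, 1, Dt2, pairs, mode), 1)
  # two pairs with ratios 0.5 and 1.5 -> mean(0.25, 0.25)
  Dt3 <- Dt
  Dt3[1, 2] <- Dt3[2, 1] <- d[1] / 0.5
  Dt3[1, 3] <- Dt3[3, 1] <- d[2] / 1.5
  expect_equal(weighted_cost(P, 1, Dt3, pairs[1:2, , drop = FALSE], mode), 0.25)
  Dt4 <- Dt; Dt4[1, 2] <- Dt4[2, 1] <- 0
  expect_error(weighted_cost(P, 1, Dt4, pairs, mode), "deduplicate")
})

test_that("the closed-form scale is optimal against a dense grid", {
  expect_equal(optimal_scale(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(optimal_scale(2 * c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(optimal_scale(c(0, 0), c(1, 1)), "collapsed")
  expect_error(optimal_scale(c(1, 1), c(0, 1)), "positive")
  set.seed(31)
  grid <- seq(0.01, 10, length.out = 2000)
  for (k in 1:20) {
    d <- runif(10, 0.05, 3); dT <- runif(10, 0.05, 3)
    s_star <- optimal_scale(d, dT)
    cost <- function(s) mean((s * d / dT - 1)^2)
    expect_lte(cost(s_star), min(sapply(grid, cost)) + 1e-12)
  }
})

test_that("scale steps interpolate and the LR schedule decays in blocks", {
  expect_equal(scale_step(1, 3, 1), 3)
  expect_equal(scale_step(1, 3, 0.5), 2)
  expect_equal(scale_step(2, 2, 0.3), 2)
  s <- scale_step(1, 3, 0.25)
  expect_true(s > 1 && s < 3)
  expect_equal(lr_schedule(0:9, 1), rep(1, 10))
  expect_equal(lr_schedule(10, 1), 0.95)
  expect_equal(lr_schedule(25, 0.1), 0.1 * 0.95^2)
  expect_true(all(diff(lr_schedule(0:100, 1)) <= 0))
})

test_that("batching partitions the ids uniformly and reproducibly", {
  ids <- paste0("t", 1:10)
  b1 <- make_batches(ids, 10, seed = 1, epoch = 1)
  expect_length(b1, 1)
  expect_setequal(b1[[1]], ids)
  b2 <- make_batches(ids, 3, seed = 1, epoch = 1)
  expect_equal(unname(sort(lengths(b2), decreasing = TRUE)), c(3, 3, 3, 1))
  expect_setequal(unlist(b2), ids)
  expect_identical(make_batches(ids, 3, seed = 1, epoch = 1), b2)
  expect_false(identical(make_batches(ids, 3, seed = 1, epoch = 2), b2))
  # empirical co-batching rate over epochs matches the closed form
  N <- 40; B <- 8; reps <- 400
  idsN <- paste0("t", 1:N)
  hits <- 0
  for (ep in 1:reps) {
    bs <- make_batches(idsN, B, seed = 5, epoch = ep)
    hits <- hits + any(vapply(bs, function(b) all(c("t1", "t2") %in% b), TRUE))
  }
  p_hat <- hits / reps
  p_exact <- 1 - cobatch_never_probability_exact(N, B, 1)
  se <- sqrt(p_exact * (1 - p_exact) / reps)
  expect_lt(abs(p_hat - p_exact), 4 * se)
})

test_that("training decreases the loss, is seed-deterministic, and epochs=0 is a no-op", {
  b <- tiny_bundle(n = 8, L = 60, seed = 41)
  m0 <- tiny_model(60, seed = 41)
  cfg0 <- training_config(epochs = 0, seed = 41)
  m_same <- train_embedding(m0, b$aln, b$tree, cfg0)
  expect_identical(m_same$par, m0$par)
  expect_equal(nrow(attr(m_same, "log")), 0)
  cfg <- training_config(epochs = 40, seed = 41)
  m1 <- train_embedding(m0, b$aln, b$tree, cfg)
  log1 <- attr(m1, "log")
  expect_lt(log1$loss[nrow(log1)], log1$loss[1])
  expect_true(all(log1$s > 0))
  m2 <- train_embedding(m0, b$aln, b$tree, cfg)
  expect_identical(attr(m2, "log"), log1)
  expect_identical(m2$par, m1$par)
})

test_that("training rejects mismatched labels and duplicate sequences", {
  b <- tiny_bundle(n = 6, L = 30, seed = 42)
  m <- tiny_model(30, seed = 42)
  aln_bad <- b$aln
  names(aln_bad$seqs)[1] <- aln_bad$ids[1] <- "not_a_leaf"
  expect_error(train_embedding(m, aln_bad, b$tree, training_config(epochs = 1)),
               "labels differ")
  seqs <- b$aln$seqs
  seqs[2] <- seqs[1]
  expect_error(train_embedding(m, alignment(seqs), b$tree,
                               training_config(epochs = 1)),
               "duplicate")
})

test_that("training log writes as TSV", {
  b <- tiny_bundle(n = 6, L = 30, seed = 43)
  m <- train_embedding(tiny_model(30, seed = 43), b$aln, b$tree,
                       training_config(epochs = 3, seed = 43))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_training_log(m, path)
  log <- utils::read.delim(path)
  expect_equal(names(log), c("epoch", "loss", "s", "lr"))
  expect_equal(nrow(log), 3)
})
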