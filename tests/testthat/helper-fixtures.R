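# Shared fixtures and independent oracles, all built in code.

# Random tangent vectors / hyperbolic points with controlled norms.
rand_tangent <- function(d, max_norm = 2) {
  v <- rnorm(d)
  v / sqrt(sum(v^2)) * runif(1, 0, max_norm)
}

# Random point in the curvature-C Poincare ball with -C||x||^2 <= cap.
rand_poincare <- function(d, C = -1, cap = 0.9) {
  x <- rnorm(d)
  x / sqrt(sum(x^2)) * sqrt(runif(1, 0, cap) / (-C))
}

# Brute-force leaf-to-leaf path length by walking parent pointers to the
# root; independent of cophenetic().
bruteforce_leaf_distance <- function(tree, a, b) {
  parent_of <- function(node) {
    e <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(e)) e else NA_integer_
  }
  path_to_root <- function(node) {
    path <- node
    repeat {
      p <- parent_of(node)
      if (is.na(p)) break
      path <- c(path, p)
      node <- p
    }
    path
  }
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  pa <- path_to_root(ia); pb <- path_to_root(ib)
  mrca <- intersect(pa, pb)[1]
  edge_len <- function(child) tree$edge.length[tree$edge[, 2] == child]
  up <- function(path) {
    stop_at <- match(mrca, path)
    if (stop_at == 1) return(0)
    sum(vapply(path[seq_len(stop_at - 1)], edge_len, 0))
  }
  up(pa) + up(pb)
}

# All non-trivial bipartitions of an unrooted tree as canonical strings;
# independent of phangorn.
bruteforce_splits <- function(tree) {
  tab <- canonical_edges(tree)
  labels <- sort(tree$tip.label)
  n <- length(labels)
  keys <- character(0)
  for (e in seq_len(nrow(tab))) {
    cl <- tab$clade[[e]]
    if (length(cl) <= 1 || length(cl) >= n - 1) next  # trivial split
    other <- setdiff(labels, cl)
    sides <- list(cl, other)
    sides <- sides[order(vapply(sides, paste, "", collapse = "|"))]
    keys <- c(keys, paste(vapply(sides, paste, "", collapse = ","), collapse = " / "))
  }
  unique(keys)
}

bruteforce_rf <- function(t1, t2) {
  s1 <- bruteforce_splits(t1); s2 <- bruteforce_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# A tiny training bundle used across tests.
tiny_bundle <- function(n = 8, L = 60, seed = 1, mu = 0.1) {
  cfg <- simulation_config(n_leaves = n, seq_length = L, seed = seed,
                           mean_branch_length = mu)
  tree <- random_binary_tree(cfg)
  aln <- simulate_jc_alignment(tree, L, seed)
  list(tree = tree, aln = aln)
}

tiny_model <- function(L, d = 2, mode = "loid", channels = 8, seed = 1) {
  encoder_init(encoder_spec(L, d, channels = rep(channels, 3), seed = seed),
               geometry_mode(mode, dim = d))
}

# Median weighted SE over all training pairs of a trained model.
training_median_wse <- function(model, aln, tree) {
  P <- embed_sequences(model, aln)
  ids <- tree$tip.label
  Dt <- leaf_distance_matrix(tree)
  prs <- t(utils::combn(length(ids), 2))
  dhat <- apply(prs, 1, function(p)
    scaled_distance(P[ids[p[1]], ], P[ids[p[2]], ], model$mode)) *
    model$normalization_factor
  stats::median(weighted_se(dhat, Dt[cbind(ids[prs[, 1]], ids[prs[, 2]])]))
}
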