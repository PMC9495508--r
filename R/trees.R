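# Newick I/O, tree distance matrices, tree-comparison metrics, query
# selection and placement-error accounting. Trees are `ape::phylo` objects
# throughout; branch lengths are in the units of the backbone tree
# (typically expected substitutions per site).

#' Parse / write newick
#'
#' Thin, validating wrappers around `ape`'s newick reader and writer.
#' Missing branch lengths are set to 0 with a warning; duplicate leaf
#' labels and unbalanced parentheses are errors. `write_newick` emits 12
#' significant digits so that round trips preserve lengths.
#'
#' @param text a newick string, or `file` a path.
#' @param file optional path to read from / write to.
#' @param tree an `ape::phylo` tree.
#' @return `parse_newick` returns an `ape::phylo`; `write_newick` a newick
#'   string (invisibly, if `file` is given).
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) stop("give exactly one of text, file")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in newick: ", n_open, " '(' vs ", n_close, " ')'")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("newick has no branch lengths; setting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths set to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 12)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Leaf-to-leaf path-length distance matrix
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return a symmetric labeled matrix of path lengths with zero diagonal
#'   and attribute `normalization_factor` (1 until normalized by
#'   [normalize_tree_distances()]).
#' @export
leaf_distance_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  D <- stats::cophenetic(tree)
  D <- D[tree$tip.label, tree$tip.label]
  attr(D, "normalization_factor") <- 1
  D
}

#' Robinson-Foulds distance between two trees
#'
#' Normalized symmetric-difference count of non-trivial bipartitions; the
#' denominator is `2 (n - 3)` (the maximum for binary trees) even for
#' non-binary inputs. The raw split count and the denominator are attached
#' as attributes so the unambiguous raw value is always available.
#'
#' @param t1,t2 trees with identical leaf label sets.
#' @return normalized RF distance in `[0, 1]`, with attributes `raw` and
#'   `denominator`.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf label sets")
  raw <- phangorn::RF.dist(t1, t2, normalize = FALSE)
  denom <- 2 * (length(t1$tip.label) - 3)
  structure(raw / denom, raw = raw, denominator = denom)
}

# Unrooted quartet topology codes for the columns of `q` (4 x m matrix of
# leaf indices) given a topological (unit-branch-length) distance matrix:
# 1 = (12|34), 2 = (13|24), 3 = (14|23), 0 = unresolved/tied.
.quartet_codes <- function(D, q) {
  s1 <- D[cbind(q[1, ], q[2, ])] + D[cbind(q[3, ], q[4, ])]
  s2 <- D[cbind(q[1, ], q[3, ])] + D[cbind(q[2, ], q[4, ])]
  s3 <- D[cbind(q[1, ], q[4, ])] + D[cbind(q[2, ], q[3, ])]
  S <- cbind(s1, s2, s3)
  lo <- pmin(s1, s2, s3)
  code <- max.col(-S, ties.method = "first")
  tied <- rowSums(S == lo) > 1L
  code[tied] <- 0L
  code
}

#' Quartet distance by Monte-Carlo sampling
#'
#' Fraction of 4-leaf subsets whose induced unrooted topologies differ
#' between the two trees. Subsets are sampled uniformly with replacement
#' (deterministically given `seed`); when the total number of quartets does
#' not exceed `n_samples` (or `exhaustive = TRUE`) all quartets are
#' enumerated instead and the value is exact.
#'
#' @param t1,t2 trees sharing a leaf set of at least 4.
#' @param n_samples number of sampled quartets (default 1e5).
#' @param seed RNG seed (mandatory for sampling).
#' @param exhaustive force exhaustive enumeration.
#' @return the (estimated) normalized quartet distance in `[0, 1]`, with
#'   attribute `exhaustive` (logical).
#' @export
sampled_quartet_distance <- function(t1, t2, n_samples = 1e5, seed = 1L,
                                     exhaustive = FALSE) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"), n_samples >= 1)
  labels <- t1$tip.label
  if (!setequal(labels, t2$tip.label))
    stop("trees have different leaf label sets")
  n <- length(labels)
  if (n < 4) stop("need at least 4 shared leaves")
  topo <- function(tr) {
    tr$edge.length <- rep(1, nrow(tr$edge))
    D <- stats::cophenetic(tr)
    D[labels, labels]
  }
  D1 <- topo(t1); D2 <- topo(t2)
  total <- choose(n, 4)
  if (exhaustive || total <= n_samples) {
    q <- utils::combn(n, 4)
    est <- mean(.quartet_codes(D1, q) != .quartet_codes(D2, q))
    return(structure(est, exhaustive = TRUE))
  }
  est <- .with_seed(seed, {
    q <- replicate(n_samples, sample.int(n, 4L))
    mean(.quartet_codes(D1, q) != .quartet_codes(D2, q))
  })
  structure(est, exhaustive = FALSE)
}

#' Random query split
#'
#' Uniformly samples a fraction of the leaves as queries (round half up)
#' and prunes them from the tree; pruning suppresses the resulting
#' degree-2 nodes and sums their branch lengths, so path lengths among the
#' surviving leaves are unchanged.
#'
#' @param tree an `ape::phylo`.
#' @param fraction fraction of leaves used as queries (default 0.05).
#' @param seed RNG seed.
#' @return `list(backbone = pruned tree, queries = character ids)`.
#' @export
random_query_split <- function(tree, fraction = 0.05, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), fraction > 0, fraction < 1)
  n <- length(tree$tip.label)
  n_q <- floor(n * fraction + 0.5)  # round half up
  n_q <- max(1L, n_q)
  if (n - n_q < 3) stop("backbone would have fewer than 3 leaves")
  queries <- .with_seed(seed, sample(tree$tip.label, n_q))
  list(backbone = ape::drop.tip(tree, queries), queries = sort(queries))
}

#' Clade-based query split
#'
#' Samples `n_clades` pairwise-disjoint clades whose leaf counts lie in
#' `[min_size, max_size]` (greedy sequential sampling over the shuffled
#' eligible clades) and removes all their leaves as queries.
#'
#' @param tree an `ape::phylo`.
#' @param n_clades number of clades to remove (default 100).
#' @param min_size,max_size clade leaf-count bounds (defaults 5, 10).
#' @param seed RNG seed.
#' @return `list(backbone, queries, clades)` where `clades` is a list of
#'   leaf-label vectors, one per selected clade.
#' @export
clade_query_split <- function(tree, n_clades = 100L, min_size = 5L,
                              max_size = 10L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), min_size >= 1, max_size >= min_size)
  n <- length(tree$tip.label)
  internal <- setdiff((n + 1L):(n + tree$Nnode), n + 1L)  # exclude the root
  clades <- lapply(internal, function(nd)
    tree$tip.label[.clade_tips(tree, nd)])
  sizes <- lengths(clades)
  eligible <- clades[sizes >= min_size & sizes <= max_size]
  chosen <- .with_seed(seed, {
    order_ <- sample.int(length(eligible))
    used <- character(0)
    keep <- list()
    for (k in order_) {
      if (length(keep) == n_clades) break
      if (!any(eligible[[k]] %in% used)) {
        keep <- c(keep, eligible[k])
        used <- c(used, eligible[[k]])
      }
    }
    keep
  })
  if (length(chosen) < n_clades)
    stop(sprintf("only %d disjoint eligible clades available (%d requested)",
                 length(chosen), n_clades))
  queries <- sort(unlist(chosen))
  backbone <- if (n - length(queries) >= 3) {
    ape::drop.tip(tree, queries)
  } else {
    warning("fewer than 3 leaves left; no backbone tree returned")
    NULL
  }
  list(backbone = backbone, queries = queries, clades = chosen)
}

# Tip indices (into tip.label) descending from node `nd`.
.clade_tips <- function(tree, nd) {
  n <- length(tree$tip.label)
  if (nd <= n) return(nd)
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  unlist(lapply(kids, .clade_tips, tree = tree))
}

#' Canonical edge table of a tree
#'
#' Edges are identified by their index in the postorder edge ordering; the
#' table records each edge's parent and child node, length, and the sorted
#' leaf labels of the child clade (which identify the edge's bipartition
#' and are stable across tools).
#'
#' @param tree an `ape::phylo`.
#' @return a data.frame with columns `edge_id`, `parent`, `child`,
#'   `length`, `is_terminal`, `child_label` (leaf label for terminal
#'   edges, NA otherwise) and list-column `clade` of child-clade labels.
#' @export
canonical_edges <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tr <- ape::reorder.phylo(tree, "postorder")
  n <- length(tr$tip.label)
  m <- nrow(tr$edge)
  clade <- vector("list", m)
  for (e in seq_len(m)) {
    ch <- tr$edge[e, 2]
    clade[[e]] <- sort(tr$tip.label[.clade_tips(tr, ch)])
  }
  data.frame(
    edge_id = seq_len(m),
    parent = tr$edge[, 1],
    child = tr$edge[, 2],
    length = if (is.null(tr$edge.length)) rep(NA_real_, m) else tr$edge.length,
    is_terminal = tr$edge[, 2] <= n,
    child_label = ifelse(tr$edge[, 2] <= n, tr$tip.label[pmin(tr$edge[, 2], n)],
                         NA_character_),
    stringsAsFactors = FALSE
  ) -> tab
  tab$clade <- clade
  tab
}

# Key identifying an edge by its unrooted bipartition: the lexicographically
# smaller side of the split, pasted. Root edges of a rooted binary tree (the
# two edges meeting at a degree-2 root) share a bipartition and hence a key.
.edge_bipartition_keys <- function(tree) {
  tab <- canonical_edges(tree)
  all_labels <- sort(tree$tip.label)
  vapply(tab$clade, function(cl) {
    other <- setdiff(all_labels, cl)
    sides <- list(cl, other)
    sides <- sides[order(vapply(sides, paste, "", collapse = "\r"))]
    paste(sides[[1]], collapse = "\r")
  }, "")
}

#' Topological error of a placement, in edges
#'
#' Counts the number of edges between the backbone edge a query was placed
#' on and the edge it truly attaches to -- the backbone edge onto which the
#' query's pendant collapses when the query is pruned from the true tree.
#' The count is taken on the unrooted backbone (the two edges meeting at a
#' degree-2 root are one unrooted edge), so a placement on the correct
#' unrooted edge scores 0. If the query truly attaches at the backbone
#' root node (no single true edge), the minimum over the root-incident
#' edges is used.
#'
#' @param true_tree the tree containing the query and all backbone leaves.
#' @param backbone the backbone tree (true tree with the query, and
#'   possibly other queries, pruned).
#' @param query leaf label of the query in `true_tree`.
#' @param placed_edge canonical edge id (see [canonical_edges()]) of the
#'   backbone edge the query was placed on.
#' @return nonnegative integer edge count; 0 iff the placement is correct.
#' @export
placement_edge_error <- function(true_tree, backbone, query, placed_edge) {
  stopifnot(inherits(true_tree, "phylo"), inherits(backbone, "phylo"))
  if (!query %in% true_tree$tip.label) stop("query is not a leaf of true_tree")
  bb_labels <- backbone$tip.label
  if (query %in% bb_labels) stop("query must not be a backbone leaf")
  restricted <- ape::keep.tip(true_tree, c(bb_labels, query))
  qi <- match(query, restricted$tip.label)
  parent <- restricted$edge[restricted$edge[, 2] == qi, 1]
  n_res <- length(restricted$tip.label)
  root_res <- n_res + 1L
  kids <- restricted$edge[restricted$edge[, 1] == parent, 2]
  sib <- setdiff(kids, qi)
  true_keys <- if (parent == root_res) {
    # query hangs off the root: with the query removed the sibling's root
    # edge vanishes; the true attachment is the backbone root node
    root_bb <- length(bb_labels) + 1L
    root_edges <- which(canonical_edges(backbone)$parent == root_bb)
    .edge_bipartition_keys(backbone)[root_edges]
  } else {
    # bipartition of the edge formed by merging the two edges around the
    # suppressed parent = the sibling clade's split
    sib_clade <- sort(restricted$tip.label[.clade_tips(restricted, sib[1])])
    if (length(sib) > 1L)
      sib_clade <- sort(unlist(lapply(sib, function(s)
        restricted$tip.label[.clade_tips(restricted, s)])))
    other <- setdiff(sort(bb_labels), sib_clade)
    sides <- list(sib_clade, other)
    sides <- sides[order(vapply(sides, paste, "", collapse = "\r"))]
    paste(sides[[1]], collapse = "\r")
  }
  keys <- .edge_bipartition_keys(backbone)
  if (placed_edge < 1 || placed_edge > length(keys))
    stop("placed_edge out of range")
  # collapse rooted edges to unrooted edges via their bipartition keys
  ukeys <- unique(keys)
  uidx <- match(keys, ukeys)
  tab <- canonical_edges(backbone)
  m <- length(ukeys)
  # unrooted adjacency: two unrooted edges are adjacent if some rooted
  # representatives share a node (the degree-2 root merges its two edges)
  adj <- vector("list", m)
  node_of <- split(seq_along(keys), uidx)
  for (a in seq_len(m - 1)) for (b in (a + 1):m) {
    ea <- node_of[[a]]; eb <- node_of[[b]]
    na <- unique(c(tab$parent[ea], tab$child[ea]))
    nb <- unique(c(tab$parent[eb], tab$child[eb]))
    if (length(intersect(na, nb))) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  bfs <- function(from) {
    dist <- rep(NA_integer_, m)
    dist[from] <- 0L
    queue <- from
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
    dist
  }
  dist <- bfs(uidx[placed_edge])
  min(dist[uidx[match(true_keys, keys)]])
}
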