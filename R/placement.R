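# Query-backbone distance tables, simplified distance-based placement,
# hybrid update matrices for tree extension, multi-gene median merging and
# PHYLIP square-matrix I/O for external tools (APPLES-2, FastME).

#' Query-to-backbone distance table
#'
#' Embeds backbone and query sequences with a trained model and returns
#' the matrix of scaled, de-normalized distances
#' `normalization_factor * s * d_unit(query, backbone)` -- i.e., distances
#' in the units of the backbone tree.
#'
#' @param model a trained `embedding_model`.
#' @param backbone_aln backbone [alignment()].
#' @param query_aln query [alignment()].
#' @return a `query x backbone` matrix with dimnames, class
#'   `query_distance_table`.
#' @export
query_distances <- function(model, backbone_aln, query_aln) {
  stopifnot(inherits(model, "embedding_model"))
  Pb <- embed_sequences(model, backbone_aln)
  Pq <- embed_sequences(model, query_aln)
  out <- .cross_unit_distances(Pq, Pb, model$mode$mode) *
    model$mode$scale * model$normalization_factor
  dimnames(out) <- list(query_aln$ids, backbone_aln$ids)
  class(out) <- c("query_distance_table", class(out))
  out
}

#' Query-to-query distances from the same model
#'
#' @param model a trained `embedding_model`.
#' @param query_aln query [alignment()].
#' @return symmetric matrix of de-normalized distances among the queries.
#' @export
query_query_distances <- function(model, query_aln) {
  Pq <- embed_sequences(model, query_aln)
  out <- .cross_unit_distances(Pq, Pq, model$mode$mode) *
    model$mode$scale * model$normalization_factor
  diag(out) <- 0
  dimnames(out) <- list(query_aln$ids, query_aln$ids)
  out
}

# matrix variant of the coincidence-clamped acosh
.acosh0m <- function(U) {
  D <- acosh(pmax(U, 1))
  D[U - 1 < 1e-12] <- 0
  D
}

# Unit-curvature distances between all rows of P (n x .) and Q (m x .),
# points already on the manifold.
.cross_unit_distances <- function(P, Q, mode) {
  switch(mode,
    loid = {
      U <- tcrossprod(P[, 1], Q[, 1]) -
        tcrossprod(P[, -1, drop = FALSE], Q[, -1, drop = FALSE])
      .acosh0m(U)
    },
    poincare = {
      np <- rowSums(P^2); nq <- rowSums(Q^2)
      D2 <- outer(np, nq, `+`) - 2 * tcrossprod(P, Q)
      U <- 1 + 2 * pmax(D2, 0) / outer(1 - np, 1 - nq)
      .acosh0m(U)
    },
    euclidean = {
      np <- rowSums(P^2); nq <- rowSums(Q^2)
      pmax(outer(np, nq, `+`) - 2 * tcrossprod(P, Q), 0)
    })
}

#' Nearest backbone references of a query
#'
#' @param table a [query_distances()] table.
#' @param q query id.
#' @param b number of references (default 5).
#' @return the `b` backbone ids with smallest distance to `q`; ties broken
#'   by lexicographic id.
#' @export
nearest_references <- function(table, q, b = 5L) {
  stopifnot(b >= 1)
  if (!q %in% rownames(table)) stop("unknown query id: ", q)
  d <- table[q, ]
  ord <- order(d, colnames(table))
  colnames(table)[ord][seq_len(min(b, ncol(table)))]
}

#' Place a query on a backbone edge by weighted least squares
#'
#' A deliberately simplified distance-based placement (production
#' pipelines export the distance table to APPLES-2 via
#' [write_phylip_matrix()]): for each candidate edge, the pendant length
#' and the attachment offset along the edge are fit by least squares
#' against the model distances to the `b` nearest references, weighted by
#' inverse squared model distances (configurable to unweighted); the edge
#' with the smallest weighted residual wins, ties broken by canonical edge
#' id. Negative pendant/offset solutions are clamped to the feasible
#' range. When all references fall on one side of a candidate edge the
#' pendant and offset are confounded; the nearest reference from the other
#' side is then added to that edge's fit to restore identifiability. When
#' several edges tie at the minimal residual (a query attaching beyond all
#' its nearest references cannot be localized by them alone), the tied
#' edges are refit against all backbone references before the tie-break.
#'
#' @param backbone backbone `ape::phylo`.
#' @param table a [query_distances()] table covering all backbone leaves.
#' @param q query id.
#' @param b number of nearest references used (default 5).
#' @param candidates `"auto"` (all edges for backbones with at most 256
#'   edges, else the path heuristic), `"all"`, or `"paths"` (edges on
#'   paths among the b nearest references plus edges incident to those
#'   paths).
#' @param weighting `"inverse_sq"` (default) or `"unweighted"`.
#' @return a list of class `placement_result`: `query`, `edge_id`
#'   (canonical id, see [canonical_edges()]), `pendant`, `offset`
#'   (distance from the edge's parent end), `residual`, `references`,
#'   `degenerate` flag.
#' @export
place_query <- function(backbone, table, q, b = 5L,
                        candidates = c("auto", "all", "paths"),
                        weighting = c("inverse_sq", "unweighted")) {
  candidates <- match.arg(candidates)
  weighting <- match.arg(weighting)
  stopifnot(inherits(backbone, "phylo"))
  labels <- backbone$tip.label
  if (!all(labels %in% colnames(table)))
    stop("distance table does not cover all backbone leaves")
  refs <- nearest_references(table, q, b)
  delta <- table[q, refs]
  tab <- canonical_edges(backbone)
  # query indistinguishable from a backbone leaf: terminal edge, pendant 0
  if (any(delta == 0)) {
    leaf <- refs[which(delta == 0)[1]]
    eid <- tab$edge_id[which(tab$is_terminal & tab$child_label == leaf)]
    return(structure(list(query = q, edge_id = eid,
                          pendant = 0, offset = tab$length[eid],
                          residual = 0, references = refs,
                          degenerate = FALSE),
                     class = "placement_result"))
  }
  m <- nrow(tab)
  cand <- if (candidates == "all" || (candidates == "auto" && m <= 256L)) {
    seq_len(m)
  } else {
    .path_candidate_edges(backbone, tab, refs)
  }
  tr <- ape::reorder.phylo(backbone, "postorder")
  ND <- ape::dist.nodes(tr)
  all_d <- table[q, tr$tip.label]
  degenerate <- all(abs(delta - delta[1]) < 1e-15)
  fit_edge <- function(e, refs_e) {
    p <- tab$parent[e]; ch <- tab$child[e]; len <- tab$length[e]
    in_clade <- refs_e %in% tab$clade[[e]]
    if (length(unique(in_clade)) == 1L) {
      # all references on one side of this edge: the pendant and the
      # offset are confounded; add the nearest reference from the other
      # side to restore identifiability
      side <- if (in_clade[1]) setdiff(tr$tip.label, tab$clade[[e]])
              else intersect(tr$tip.label, tab$clade[[e]])
      side <- setdiff(side, refs_e)
      if (length(side)) {
        add <- side[order(all_d[side], side)][1]
        refs_e <- c(refs_e, add)
        in_clade <- refs_e %in% tab$clade[[e]]
      }
    }
    delta_e <- table[q, refs_e]
    w <- if (weighting == "inverse_sq") 1 / delta_e^2 else rep(1, length(delta_e))
    ref_idx <- match(refs_e, tr$tip.label)
    # predicted distance: pendant y + offset term + node-to-leaf distance
    # child side: y + (len - x) + D[child, i];  parent side: y + x + D[parent, i]
    sgn <- ifelse(in_clade, -1, 1)
    k <- ifelse(in_clade, len + ND[ch, ref_idx], ND[p, ref_idx])
    .wls_pendant_offset(delta_e, k, sgn, w, len)
  }
  fits <- lapply(cand, fit_edge, refs_e = refs)
  resid <- vapply(fits, `[[`, 0, "residual")
  best_res <- min(resid)
  tied <- which(resid <= best_res + 1e-12 * (1 + best_res))
  if (length(tied) > 1L && length(refs) < length(tr$tip.label)) {
    # residual tie: a query attaching beyond all its nearest references
    # cannot be localized by them alone; refit the tied edges against all
    # backbone references to break the tie
    fits[tied] <- lapply(cand[tied], fit_edge, refs_e = tr$tip.label)
    resid[tied] <- vapply(fits[tied], `[[`, 0, "residual")
    resid[-tied] <- Inf
    best_res <- min(resid)
    tied <- which(resid <= best_res + 1e-12 * (1 + best_res))
  }
  pick <- tied[which.min(cand[tied])]   # remaining ties: canonical edge id
  best <- fits[[pick]]
  structure(list(query = q, edge_id = cand[pick], pendant = best$y,
                 offset = best$x, residual = best$residual,
                 references = refs, degenerate = degenerate),
            class = "placement_result")
}

# Weighted least squares for delta_i ~ y + sgn_i * x + k_i with y >= 0 and
# 0 <= x <= len.
.wls_pendant_offset <- function(delta, k, sgn, w, len) {
  z <- delta - k
  sw <- sum(w); swsgn <- sum(w * sgn); sws2 <- sum(w)  # sgn^2 = 1
  a11 <- sw; a12 <- swsgn; a22 <- sws2
  b1 <- sum(w * z); b2 <- sum(w * sgn * z)
  det <- a11 * a22 - a12^2
  if (abs(det) < 1e-12 * a11 * a22 || det <= 0) {
    # references all on one side: x and y are confounded; fix x at the
    # parent end and fit y alone
    x <- if (all(sgn < 0)) len else 0
    y <- max(sum(w * (z - sgn * x)) / sw, 0)
  } else {
    y <- (b1 * a22 - b2 * a12) / det
    x <- (a11 * b2 - a12 * b1) / det
    x <- min(max(x, 0), len)
    y <- max(sum(w * (z - sgn * x)) / sw, 0)
  }
  pred <- y + sgn * x + k
  list(y = y, x = x, residual = sum(w * (pred - delta)^2))
}

# Candidate edges: edges on the paths among the b nearest references plus
# edges incident to any node on those paths.
.path_candidate_edges <- function(backbone, tab, refs) {
  tr <- ape::reorder.phylo(backbone, "postorder")
  ref_idx <- match(refs, tr$tip.label)
  # nodes on paths: union over pairs of the nodes on the path
  nodes <- integer(0)
  np <- ape::nodepath
  for (a in seq_along(ref_idx)) for (b2 in seq_along(ref_idx)) {
    if (a < b2) nodes <- union(nodes, np(tr, ref_idx[a], ref_idx[b2]))
  }
  on_path <- (tab$parent %in% nodes) | (tab$child %in% nodes)
  which(on_path)
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement> %s -> edge %d (pendant %.4g, offset %.4g, residual %.4g)%s\n",
              x$query, x$edge_id, x$pendant, x$offset, x$residual,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Place all queries of a distance table
#'
#' @inheritParams place_query
#' @return a data.frame with one row per query: query, edge_id, pendant,
#'   offset, residual, degenerate.
#' @export
place_all <- function(backbone, table, b = 5L, ...) {
  res <- lapply(rownames(table), function(q)
    place_query(backbone, table, q, b = b, ...))
  data.frame(query = vapply(res, `[[`, "", "query"),
             edge_id = vapply(res, `[[`, 0L, "edge_id"),
             pendant = vapply(res, `[[`, 0, "pendant"),
             offset = vapply(res, `[[`, 0, "offset"),
             residual = vapply(res, `[[`, 0, "residual"),
             degenerate = vapply(res, `[[`, FALSE, "degenerate"),
             stringsAsFactors = FALSE)
}

#' Query distance table from true tree distances
#'
#' Builds the table [place_query()] consumes directly from the path
#' lengths of a tree containing both the queries and the backbone leaves:
#' the additive-distance oracle (placement from such a table recovers the
#' true attachment edge exactly).
#'
#' @param true_tree tree containing backbone leaves and queries.
#' @param backbone the backbone tree (its leaves select the columns).
#' @param queries character vector of query leaf labels.
#' @return a `query_distance_table`.
#' @export
true_distance_table <- function(true_tree, backbone, queries) {
  D <- leaf_distance_matrix(true_tree)
  if (!all(queries %in% rownames(D))) stop("queries missing from true_tree")
  if (!all(backbone$tip.label %in% rownames(D)))
    stop("backbone leaves missing from true_tree")
  out <- D[queries, backbone$tip.label, drop = FALSE]
  class(out) <- c("query_distance_table", class(out))
  out
}

#' Graft a placed query onto the backbone
#'
#' Attaches the query as a new leaf on the placement's edge, at the fitted
#' offset from the edge's parent end, with the fitted pendant length.
#'
#' @param backbone backbone `ape::phylo`.
#' @param q query id.
#' @param placement a [place_query()] result.
#' @return the extended tree.
#' @export
attach_query <- function(backbone, q, placement) {
  stopifnot(inherits(placement, "placement_result"))
  tab <- canonical_edges(backbone)
  e <- placement$edge_id
  len <- tab$length[e]
  pos <- min(max(len - placement$offset, 0), len)  # distance above the child
  phytools::bind.tip(backbone, q, edge.length = placement$pendant,
                     where = tab$child[e], position = pos)
}

#' Hybrid update matrix for tree extension
#'
#' Builds the full symmetric matrix over backbone plus query taxa whose
#' backbone-backbone block is the exact tree distance matrix and whose
#' query-backbone and query-query blocks come from the embedding model;
#' the input of FastME/APPLES-style tree updating.
#'
#' @param backbone backbone `ape::phylo`.
#' @param table a [query_distances()] table (query x backbone).
#' @param query_query symmetric matrix of query-query embedding distances
#'   (see [query_query_distances()]); required when there is more than one
#'   query.
#' @return a labeled symmetric matrix, backbone taxa first.
#' @export
build_update_matrix <- function(backbone, table, query_query = NULL) {
  stopifnot(inherits(backbone, "phylo"))
  Db <- leaf_distance_matrix(backbone)
  bb <- rownames(Db)
  qq <- rownames(table)
  if (!setequal(colnames(table), bb))
    stop("table backbone ids do not match the backbone tree")
  if (length(qq) > 1 && is.null(query_query))
    stop("query_query distances required for more than one query")
  n <- length(bb) + length(qq)
  out <- matrix(0, n, n, dimnames = list(c(bb, qq), c(bb, qq)))
  out[bb, bb] <- Db[bb, bb]
  out[qq, bb] <- table[qq, bb, drop = FALSE]
  out[bb, qq] <- t(table[qq, bb, drop = FALSE])
  if (length(qq) > 1) {
    if (!setequal(rownames(query_query), qq))
      stop("query_query ids do not match the table's queries")
    out[qq, qq] <- query_query[qq, qq]
    diag(out) <- 0
  }
  out
}

#' Merge per-gene distance matrices by the entrywise median
#'
#' For multi-gene updating, one model is trained per gene and the final
#' distance for each pair is the median across genes (the lower median for
#' an even number of genes, for determinism).
#'
#' @param matrices a list of identically labeled matrices.
#' @return the entrywise (lower) median matrix.
#' @export
merge_gene_matrices <- function(matrices) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  ref <- matrices[[1]]
  for (m in matrices[-1]) {
    if (!identical(dim(m), dim(ref)) ||
        !identical(dimnames(m), dimnames(ref)))
      stop("matrices must share dimensions and labels")
  }
  if (length(matrices) == 1L) return(ref)
  arr <- simplify2array(matrices)
  k <- floor((length(matrices) + 1) / 2)  # lower median
  out <- apply(arr, c(1, 2), function(v) sort(v)[k])
  dimnames(out) <- dimnames(ref)
  out
}

#' PHYLIP square distance matrix I/O
#'
#' Writes/reads the full square PHYLIP dialect consumed by FastME and
#' APPLES: a first line with the taxon count, then one line per taxon,
#' `label  d1 d2 ...`, with 10 significant digits. Labels containing
#' whitespace are rejected.
#'
#' @param m a square labeled symmetric matrix.
#' @param path file path.
#' @return `write_phylip_matrix` returns `path` invisibly;
#'   `read_phylip_matrix` the labeled matrix.
#' @export
write_phylip_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  labels <- rownames(m)
  if (is.null(labels)) stop("matrix must have row labels")
  if (any(grepl("\\s", labels))) stop("labels must not contain whitespace")
  lines <- c(sprintf("%d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(labels[i],
                       formatC(m[i, ], format = "g", digits = 10)),
                     collapse = " "), ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("first line must be the taxon count")
  if (length(lines) - 1L != n)
    stop(sprintf("header says %d taxa but file has %d rows", n, length(lines) - 1L))
  labels <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != n + 1L)
      stop(sprintf("row %d has %d values, expected %d", i, length(parts) - 1L, n))
    labels[i] <- parts[1]
    m[i, ] <- as.numeric(parts[-1])
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Write placements as tab-separated text
#'
#' A jplace-lite TSV: query id, canonical edge id, pendant length, offset
#' from the parent end of the edge, and the least-squares residual.
#'
#' @param placements a data.frame from [place_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_placements <- function(placements, path) {
  utils::write.table(placements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
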