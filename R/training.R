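# Training: the weighted relative-distance objective, closed-form scale
# updates, tree-distance normalization, pseudo-counts, the exponential
# learning-rate schedule and the mini-batch loop.
#
# The objective is the mean over distinct leaf pairs of
#   (s * d(phi(s_i), phi(s_j)) / dT(i, j) - 1)^2,
# with d the unit-curvature distance of the active geometry and s a global
# scale (s = 1/sqrt(-C) in the hyperbolic modes). For a fixed embedding the
# objective is convex in s with closed-form minimizer
#   s* = E[d/dT] / E[(d/dT)^2],
# so training alternates gradient steps on the encoder with damped steps of
# the scale toward s*.

#' Training configuration
#'
#' @param batch_size mini-batch size B (default 32; batch sizes around 64
#'   were found to minimize overall distortion).
#' @param epochs number of epochs (default 1000).
#' @param alpha0 initial learning rate (default 1e-3).
#' @param decay_p learning-rate decay factor per block (default 0.95).
#' @param decay_K epochs per constant-rate block (default 10).
#' @param scale_lr_coupled if TRUE (default) the scale step reuses the
#'   network learning-rate schedule as its damping factor; otherwise
#'   `scale_alpha` is used throughout.
#' @param scale_alpha fixed scale damping when `scale_lr_coupled = FALSE`.
#' @param scale_per update the scale per `"batch"` (default) or per
#'   `"epoch"`.
#' @param optimizer `"sgd"` (plain stochastic gradient descent, default)
#'   or `"adam"`.
#' @param pseudo_count nonnegative length added to every terminal branch
#'   before computing training distances (default 0).
#' @param seed RNG seed governing batching (and any other training
#'   randomness).
#' @return an object of class `training_config`.
#' @export
training_config <- function(batch_size = 32L, epochs = 1000L, alpha0 = 1e-3,
                            decay_p = 0.95, decay_K = 10L,
                            scale_lr_coupled = TRUE, scale_alpha = 1e-3,
                            scale_per = c("batch", "epoch"),
                            optimizer = c("sgd", "adam"),
                            pseudo_count = 0, seed = 1L) {
  scale_per <- match.arg(scale_per)
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 2, epochs >= 0, alpha0 > 0,
            decay_p > 0, decay_p < 1, decay_K >= 1, pseudo_count >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), alpha0 = alpha0,
                 decay_p = decay_p, decay_K = as.integer(decay_K),
                 scale_lr_coupled = isTRUE(scale_lr_coupled),
                 scale_alpha = scale_alpha, scale_per = scale_per,
                 optimizer = optimizer, pseudo_count = pseudo_count,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Normalize tree distances to a maximum of 1
#'
#' Divides the distance matrix by its maximum entry and records the factor
#' (for de-normalizing model distances back to tree units). Normalizing
#' keeps embedded points away from the representable-distance limit of the
#' unit-curvature models; the factor is absorbed into the scale.
#'
#' @param D a distance matrix from [leaf_distance_matrix()].
#' @return the normalized matrix with attribute `normalization_factor`.
#' @export
normalize_tree_distances <- function(D) {
  mx <- max(D)
  if (mx <= 0) stop("all tree distances are zero; cannot normalize")
  out <- D / mx
  attr(out, "normalization_factor") <- mx * (attr(D, "normalization_factor") %||% 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add pseudo-counts to terminal branches
#'
#' Lengthens every leaf-incident branch by `eps`, which increases every
#' leaf-pair distance by exactly `2 * eps`. Used to lift very small
#' distances away from zero before training.
#'
#' @param tree an `ape::phylo`.
#' @param eps nonnegative length added to each terminal branch.
#' @return the adjusted tree.
#' @export
add_terminal_pseudocounts <- function(tree, eps) {
  stopifnot(inherits(tree, "phylo"), eps >= 0)
  if (eps == 0) return(tree)
  terminal <- tree$edge[, 2] <= length(tree$tip.label)
  tree$edge.length[terminal] <- tree$edge.length[terminal] + eps
  tree
}

#' Weighted relative-distance cost
#'
#' Mean over the given pairs of `(s * d / dT - 1)^2`, where `d` is the
#' unit-curvature distance between the embedded points of the pair.
#'
#' @param embedded matrix of embedded points, one per row (as returned by
#'   [embed_sequences()]): 'Loid, Poincare or Euclidean points according
#'   to `mode`.
#' @param s positive scale.
#' @param Dtree matrix of tree distances, rows/cols aligned with
#'   `embedded` rows.
#' @param pairs two-column integer matrix of distinct row-index pairs.
#' @param mode a [geometry_mode()] (only its `mode` field is used; the
#'   scale is passed explicitly).
#' @return the mean weighted squared error.
#' @export
weighted_cost <- function(embedded, s, Dtree, pairs, mode) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2, s > 0)
  i <- pairs[, 1]; j <- pairs[, 2]
  dT <- Dtree[cbind(i, j)]
  if (any(dT <= 0))
    stop("zero tree distance among training pairs (duplicate taxa?); ",
         "deduplicate sequences or add terminal pseudo-counts")
  d <- .embedded_pair_distances(embedded, i, j, mode$mode)
  mean((s * d / dT - 1)^2)
}

# Unit-curvature distances between embedded points (post exponential map).
.embedded_pair_distances <- function(P, i, j, mode) {
  switch(mode,
    loid = {
      # -x' H y = x1 y1 - <spatial>
      u <- P[i, 1] * P[j, 1] -
        rowSums(P[i, -1, drop = FALSE] * P[j, -1, drop = FALSE])
      .acosh0(u)
    },
    poincare = {
      nx <- rowSums(P^2)
      D2 <- rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2)
      .acosh0(1 + 2 * D2 / ((1 - nx[i]) * (1 - nx[j])))
    },
    euclidean = rowSums((P[i, , drop = FALSE] - P[j, , drop = FALSE])^2))
}

#' Closed-form optimal scale
#'
#' The global minimizer of the weighted cost in `s` for a fixed embedding:
#' `E[d/dT] / E[(d/dT)^2]` over the given distance pairs.
#'
#' @param embedded_d unit-curvature embedding distances.
#' @param tree_d matching positive tree distances.
#' @return the optimal scale (positive).
#' @export
optimal_scale <- function(embedded_d, tree_d) {
  stopifnot(length(embedded_d) == length(tree_d))
  if (any(tree_d <= 0)) stop("tree distances must be positive")
  if (all(embedded_d == 0))
    stop("all embedding distances are zero (collapsed embedding)")
  r <- embedded_d / tree_d
  mean(r) / mean(r^2)
}

#' Damped scale update
#'
#' `s_{k+1} = s_k + alpha_k (s* - s_k)`: a convex combination of the
#' current scale and the closed-form optimum.
#'
#' @param s_k current scale.
#' @param s_star closed-form optimal scale for the current embedding.
#' @param alpha_k step size in (0, 1].
#' @return the updated scale.
#' @export
scale_step <- function(s_k, s_star, alpha_k) {
  stopifnot(s_k > 0, s_star > 0, alpha_k > 0, alpha_k <= 1)
  s_k + alpha_k * (s_star - s_k)
}

#' Exponentially decaying learning-rate schedule
#'
#' Piecewise-constant over blocks of `K` epochs:
#' `alpha_k = alpha0 * p^floor(k / K)` for 0-based epoch `k`.
#'
#' @param k epoch index (0-based).
#' @param alpha0 initial rate.
#' @param K block length in epochs (default 10).
#' @param p_decay decay factor per block (default 0.95).
#' @return the learning rate at epoch `k`.
#' @export
lr_schedule <- function(k, alpha0, K = 10L, p_decay = 0.95) {
  stopifnot(all(k >= 0))
  alpha0 * p_decay^(k %/% K)
}

#' Random batch partition for one epoch
#'
#' Uniformly partitions the ids into consecutive batches of size `B` (last
#' batch possibly smaller); a fresh partition per epoch, deterministic
#' given `(seed, epoch)`.
#'
#' @param ids character vector of leaf ids.
#' @param B batch size (>= 2).
#' @param seed base RNG seed.
#' @param epoch epoch index.
#' @return list of character vectors, one per batch.
#' @export
make_batches <- function(ids, B, seed = 1L, epoch = 0L) {
  stopifnot(B >= 2)
  perm <- .with_seed(.derive_seed(seed, epoch), sample(ids))
  split(perm, ceiling(seq_along(perm) / B))
}

# ---- loss gradient w.r.t. encoder outputs ---------------------------------

# V: n x d encoder outputs (pre exponential map). Returns the loss over the
# pairs and its gradient w.r.t. V, plus the unit-curvature pair distances.
.loss_and_grad <- function(V, s, dT, i, j, mode) {
  n <- nrow(V); d <- .pair_unit_distances(V, i, j, mode)
  np <- length(i)
  resid <- s * d / dT - 1
  loss <- mean(resid^2)
  cw <- 2 * resid * s / dT / np           # dL/dd per pair
  if (mode == "euclidean") {
    diff <- V[i, , drop = FALSE] - V[j, , drop = FALSE]
    Gi <- cw * 2 * diff
    dV <- .scatter_rows(rbind(Gi, -Gi), c(i, j), n, ncol(V))
    return(list(loss = loss, dV = dV, d = d))
  }
  r <- sqrt(rowSums(V^2))
  if (mode == "loid") {
    g <- ifelse(r < 1e-8, 1 + r^2 / 6, sinh(r) / r)
    gpr <- ifelse(r < 1e-4, 1 / 3 + r^2 / 30, (r * cosh(r) - sinh(r)) / r^3)  # g'(r)/r
    S <- rowSums(V[i, , drop = FALSE] * V[j, , drop = FALSE])
    u <- cosh(r[i]) * cosh(r[j]) - g[i] * g[j] * S
    dddu <- 1 / sqrt(pmax(u^2 - 1, 1e-12))
    cc <- cw * dddu
    ai <- g[i] * cosh(r[j]) - gpr[i] * g[j] * S
    aj <- g[j] * cosh(r[i]) - gpr[j] * g[i] * S
    b <- -g[i] * g[j]
    Gi <- cc * (ai * V[i, , drop = FALSE] + b * V[j, , drop = FALSE])
    Gj <- cc * (aj * V[j, , drop = FALSE] + b * V[i, , drop = FALSE])
  } else {  # poincare
    g <- ifelse(r < 1e-8, 1 - r^2 / 3, tanh(r) / r)
    # g'(r)/r with g = tanh(r)/r
    gpr <- ifelse(r < 1e-4, -2 / 3 + 2 * r^2 / 5,
                  (r / cosh(r)^2 - tanh(r)) / r^3)
    X <- V * g
    nx <- rowSums(X^2)
    XD <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
    D2 <- rowSums(XD^2)
    Ai <- 1 - nx[i]; Aj <- 1 - nx[j]
    u <- 1 + 2 * D2 / (Ai * Aj)
    dddu <- 1 / sqrt(pmax(u^2 - 1, 1e-12))
    cc <- cw * dddu
    # du/dx_i = 4 (x_i - x_j)/(Ai Aj) + 4 D2 x_i / (Ai^2 Aj)
    dUXi <- 4 * XD / (Ai * Aj) + (4 * D2 / (Ai^2 * Aj)) * X[i, , drop = FALSE]
    dUXj <- -4 * XD / (Ai * Aj) + (4 * D2 / (Ai * Aj^2)) * X[j, , drop = FALSE]
    # chain through x = g(r) v: du/dv = g du/dx + (g'(r)/r) (v . du/dx) v
    Vi <- V[i, , drop = FALSE]; Vj <- V[j, , drop = FALSE]
    Gi <- cc * (g[i] * dUXi + gpr[i] * rowSums(Vi * dUXi) * Vi)
    Gj <- cc * (g[j] * dUXj + gpr[j] * rowSums(Vj * dUXj) * Vj)
  }
  dV <- .scatter_rows(rbind(Gi, Gj), c(i, j), n, ncol(V))
  list(loss = loss, dV = dV, d = d)
}

# Accumulate rows of `contrib` into an n x d matrix by row index.
.scatter_rows <- function(contrib, idx, n, d) {
  out <- matrix(0, n, d)
  acc <- rowsum(contrib, idx)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

# ---- the training loop ----------------------------------------------------

#' Train an embedding model on a backbone tree and alignment
#'
#' Minimizes the weighted relative-distance cost over the backbone leaves
#' by mini-batch gradient descent on the encoder parameters, alternating
#' with damped closed-form updates of the scale. Tree distances are
#' normalized to a maximum of 1 and the factor stored on the model; the
#' initial scale is the closed-form optimum for the untrained embedding.
#'
#' @param model an [encoder_init()] model.
#' @param aln training [alignment()]; ids must equal the tree's leaf
#'   labels. Duplicate sequences are rejected (deduplicate or use
#'   pseudo-counts on a modified input).
#' @param tree backbone `ape::phylo` with branch lengths.
#' @param cfg a [training_config()].
#' @param verbose print a progress line every 100 epochs.
#' @return the trained model, with attribute `log`: a data.frame with
#'   columns epoch, loss (epoch mean), s, lr. `cfg$epochs = 0` returns the
#'   model unchanged with an empty log.
#' @export
train_embedding <- function(model, aln, tree, cfg = training_config(),
                            verbose = FALSE) {
  stopifnot(inherits(model, "embedding_model"), inherits(aln, "hp_alignment"),
            inherits(tree, "phylo"), inherits(cfg, "training_config"))
  ids <- tree$tip.label
  if (!setequal(ids, aln$ids))
    stop("alignment ids and tree leaf labels differ: ",
         paste(union(setdiff(ids, aln$ids), setdiff(aln$ids, ids)), collapse = ", "))
  if (anyDuplicated(aln$seqs))
    stop("duplicate training sequences detected; deduplicate the alignment")
  tree <- add_terminal_pseudocounts(tree, cfg$pseudo_count)
  Dt <- normalize_tree_distances(leaf_distance_matrix(tree))
  model$normalization_factor <- attr(Dt, "normalization_factor")
  model$backbone_ids <- ids
  n <- length(ids)
  mode <- model$mode$mode
  X_all <- .encode_batch(aln, ids)
  L <- aln$length
  # initial scale: closed-form optimum on the untrained embedding, all pairs
  V0 <- .nn_forward(model$par, model$spec, X_all, n)$V
  all_pairs <- t(utils::combn(n, 2L))
  d0 <- .pair_unit_distances(V0, all_pairs[, 1], all_pairs[, 2], mode)
  dT0 <- Dt[all_pairs]
  if (any(dT0 <= 0))
    stop("zero tree distance between distinct leaves; ",
         "add terminal pseudo-counts (cfg$pseudo_count) or deduplicate")
  s <- optimal_scale(pmax(d0, 1e-12), dT0)
  if (cfg$epochs == 0L) {
    model$mode$scale <- s
    attr(model, "log") <- data.frame(epoch = integer(0), loss = numeric(0),
                                     s = numeric(0), lr = numeric(0))
    return(model)
  }
  par <- model$par
  opt_state <- if (cfg$optimizer == "adam")
    list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
         t = 0L)
  log <- vector("list", cfg$epochs)
  col_of <- function(batch_ids) {
    bi <- match(batch_ids, ids)
    as.vector(outer(seq_len(L), (bi - 1L) * L, `+`))
  }
  for (ep in seq_len(cfg$epochs)) {
    lr <- lr_schedule(ep - 1L, cfg$alpha0, cfg$decay_K, cfg$decay_p)
    s_alpha <- if (cfg$scale_lr_coupled) min(lr, 1) else cfg$scale_alpha
    batches <- make_batches(ids, cfg$batch_size, cfg$seed, ep)
    ep_loss <- 0; ep_pairs <- 0L
    epoch_d <- c(); epoch_dT <- c()
    for (batch in batches) {
      B <- length(batch)
      if (B < 2L) next
      Xb <- X_all[, col_of(batch), drop = FALSE]
      cache <- .nn_forward(par, model$spec, Xb, B, keep_cache = TRUE)
      pr <- t(utils::combn(B, 2L))
      dTb <- Dt[cbind(match(batch[pr[, 1]], ids), match(batch[pr[, 2]], ids))]
      lg <- .loss_and_grad(cache$V, s, dTb, pr[, 1], pr[, 2], mode)
      if (!is.finite(lg$loss))
        stop("non-finite training loss at epoch ", ep,
             "; reduce the learning rate or check for collapsed embeddings")
      grads <- .nn_backward(par, model$spec, cache, lg$dV)
      par <- .opt_step(par, grads, lr, cfg$optimizer, opt_state)
      if (cfg$optimizer == "adam") opt_state <- attr(par, "state")
      if (cfg$scale_per == "batch") {
        s_star <- optimal_scale(pmax(lg$d, 1e-12), dTb)
        s <- max(scale_step(s, s_star, s_alpha), 1e-12)
      } else {
        epoch_d <- c(epoch_d, lg$d); epoch_dT <- c(epoch_dT, dTb)
      }
      ep_loss <- ep_loss + lg$loss * nrow(pr)
      ep_pairs <- ep_pairs + nrow(pr)
    }
    if (cfg$scale_per == "epoch" && length(epoch_d)) {
      s_star <- optimal_scale(pmax(epoch_d, 1e-12), epoch_dT)
      s <- max(scale_step(s, s_star, s_alpha), 1e-12)
    }
    log[[ep]] <- data.frame(epoch = ep, loss = ep_loss / max(ep_pairs, 1L),
                            s = s, lr = lr)
    if (verbose && ep %% 100 == 0)
      message(sprintf("epoch %d  loss %.5g  s %.5g  lr %.3g",
                      ep, ep_loss / max(ep_pairs, 1L), s, lr))
  }
  model$par <- par
  model$mode$scale <- s
  attr(model, "log") <- do.call(rbind, log)
  model
}

# One optimizer step; for adam, the updated state is attached as an
# attribute on the returned parameter list.
.opt_step <- function(par, grads, lr, optimizer, state) {
  if (optimizer == "sgd") {
    out <- mapply(function(p, g) p - lr * g, par, grads, SIMPLIFY = FALSE)
    return(out)
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  state$m <- mapply(function(m, g) b1 * m + (1 - b1) * g, state$m, grads,
                    SIMPLIFY = FALSE)
  state$v <- mapply(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads,
                    SIMPLIFY = FALSE)
  mhat <- lapply(state$m, function(m) m / (1 - b1^state$t))
  vhat <- lapply(state$v, function(v) v / (1 - b2^state$t))
  out <- mapply(function(p, m, v) p - lr * m / (sqrt(v) + eps),
                par, mhat, vhat, SIMPLIFY = FALSE)
  attr(out, "state") <- state
  out
}

#' Write a training log as tab-separated text
#'
#' @param model a trained model (or its `log` attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  log <- if (is.data.frame(model)) model else attr(model, "log")
  if (is.null(log)) stop("model has no training log")
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
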