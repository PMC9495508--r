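# The convolutional sequence encoder: a Euclidean network mapping one-hot
# encoded alignments to d-dimensional vectors, composed with an exponential
# map into the chosen geometry.
#
# Architecture (kernel sizes fixed at 1, 5, 5):
#   conv(k=1) -> relu -> conv(k=5) -> relu -> [conv(k=5) + skip] -> relu
#   -> flatten -> fully connected -> R^d
# The skip connection adds the second layer's output into the third layer's
# output (a residual block), which requires equal channel counts in layers
# 2 and 3. Convolutions are 1-D along the alignment with stride 1 and
# length-preserving zero padding, implemented as shifted GEMMs so the whole
# batch is processed with a handful of BLAS calls.

#' Encoder architecture specification
#'
#' @param input_length alignment length L.
#' @param embed_dim output dimension d (>= 2).
#' @param channels integer vector of three conv channel widths; the second
#'   and third must be equal (residual addition). Default `c(64, 64, 64)`.
#' @param activation apply a ReLU between blocks (default TRUE).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `encoder_spec`.
#' @export
encoder_spec <- function(input_length, embed_dim, channels = c(64L, 64L, 64L),
                         activation = TRUE, seed = 1L) {
  input_length <- as.integer(input_length)
  embed_dim <- as.integer(embed_dim)
  channels <- as.integer(channels)
  stopifnot(input_length >= 1L, length(channels) == 3L, all(channels >= 1L))
  if (embed_dim < 2L) stop("embed_dim must be >= 2")
  if (channels[2] != channels[3])
    stop("channels 2 and 3 must be equal for the residual skip connection")
  structure(list(input_length = input_length, embed_dim = embed_dim,
                 channels = channels, kernel_sizes = c(1L, 5L, 5L),
                 residual = TRUE, activation = isTRUE(activation),
                 seed = as.integer(seed)),
            class = "encoder_spec")
}

#' Initialize an embedding model
#'
#' Creates an untrained embedding model: encoder parameters drawn from
#' fan-in-scaled (He) normal initialization under the spec's seed, plus the
#' geometry the embeddings live in. Deterministic given the seed.
#'
#' @param spec an [encoder_spec()].
#' @param mode a [geometry_mode()]; its `dim` must equal `spec$embed_dim`.
#' @param normalization_factor the factor by which training tree distances
#'   were divided (set by [train_embedding()]; default 1).
#' @return an object of class `embedding_model`.
#' @export
encoder_init <- function(spec, mode = geometry_mode("loid", dim = spec$embed_dim),
                         normalization_factor = 1) {
  stopifnot(inherits(spec, "encoder_spec"), inherits(mode, "geometry_mode"))
  if (mode$dim != spec$embed_dim)
    stop("geometry dimension must equal the encoder's embed_dim")
  C1 <- spec$channels[1]; C2 <- spec$channels[2]; C3 <- spec$channels[3]
  L <- spec$input_length; d <- spec$embed_dim
  par <- .with_seed(spec$seed, {
    he <- function(nout, nin_eff, n) matrix(rnorm(nout * n, sd = sqrt(2 / nin_eff)), nrow = nout)
    list(
      W1 = he(C1, 4, 4), b1 = numeric(C1),
      W2 = array(rnorm(C2 * C1 * 5, sd = sqrt(2 / (C1 * 5))), dim = c(C2, C1, 5)),
      b2 = numeric(C2),
      W3 = array(rnorm(C3 * C2 * 5, sd = sqrt(2 / (C2 * 5))), dim = c(C3, C2, 5)),
      b3 = numeric(C3),
      Wfc = matrix(rnorm(d * C3 * L, sd = sqrt(1 / (C3 * L))), nrow = d),
      bfc = numeric(d)
    )
  })
  structure(list(spec = spec, mode = mode, par = par,
                 normalization_factor = normalization_factor,
                 backbone_ids = NULL, version = 1L),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> L = %d, d = %d, channels = (%s), %s mode, s = %g\n",
              x$spec$input_length, x$spec$embed_dim,
              paste(x$spec$channels, collapse = ", "),
              x$mode$mode, x$mode$scale))
  invisible(x)
}

# ---- batched network forward / backward -----------------------------------

# 1-D convolution, kernel 5, zero padding 2, over a batch laid out as
# C_in x (B*L). W: C_out x C_in x 5. Implemented as one GEMM on the
# im2col-stacked input (5*C_in x B*L); the stacked input and the padded
# column index of each output column are cached for the backward pass.
.conv5_forward <- function(X, W, b, B, L) {
  Cin <- nrow(X)
  Cout <- dim(W)[1]
  Lp <- L + 4L
  pad <- matrix(0, Cin, B * Lp)
  cols <- as.vector(outer(2L + seq_len(L), (seq_len(B) - 1L) * Lp, `+`))
  pad[, cols] <- X
  Z <- matrix(0, 5L * Cin, B * L)
  for (k in 1:5) Z[((k - 1L) * Cin + 1L):(k * Cin), ] <- pad[, cols + (k - 3L)]
  Wstack <- matrix(W, nrow = Cout)  # C_out x (C_in*5), k-major blocks
  # array W is (Cout, Cin, k) so matrix(W) lays out blocks k-major matching Z
  out <- Wstack %*% Z + b
  list(out = out, Z = Z, cols = cols, B = B, L = L)
}

# Backward for .conv5_forward: returns gradient w.r.t. the unpadded input
# plus parameter gradients.
.conv5_backward <- function(dOut, W, cache) {
  Cout <- dim(W)[1]; Cin <- dim(W)[2]
  B <- cache$B; L <- cache$L
  Wstack <- matrix(W, nrow = Cout)
  dZ <- crossprod(Wstack, dOut)                       # (5*Cin) x (B*L)
  dWstack <- tcrossprod(dOut, cache$Z)                # Cout x (5*Cin)
  cols <- cache$cols
  dPad <- matrix(0, Cin, B * (L + 4L))
  for (k in 1:5) {
    ck <- cols + (k - 3L)
    dPad[, ck] <- dPad[, ck] + dZ[((k - 1L) * Cin + 1L):(k * Cin), ]
  }
  list(dX = dPad[, cols, drop = FALSE],
       dW = array(dWstack, dim = dim(W)), db = rowSums(dOut))
}

# Full forward pass over a batch. X: 4 x (B*L) one-hot matrix. Returns the
# B x d output matrix and (optionally) the cache needed for backprop.
.nn_forward <- function(par, spec, X, B, keep_cache = FALSE) {
  L <- spec$input_length
  act <- spec$activation
  a1 <- par$W1 %*% X + par$b1
  z1 <- if (act) pmax(a1, 0) else a1
  c2 <- .conv5_forward(z1, par$W2, par$b2, B, L)
  z2 <- if (act) pmax(c2$out, 0) else c2$out
  c3 <- .conv5_forward(z2, par$W3, par$b3, B, L)
  a3 <- c3$out + z2                       # residual skip
  z3 <- if (act) pmax(a3, 0) else a3
  Fmat <- matrix(z3, nrow = nrow(z3) * L, ncol = B)   # per-sequence flatten
  V <- t(par$Wfc %*% Fmat + par$bfc)                  # B x d
  if (!keep_cache) return(list(V = V))
  list(V = V, X = X, a1 = a1, z1 = z1, c2 = c2, z2 = z2, c3 = c3, a3 = a3,
       z3 = z3, Fmat = Fmat)
}

# Backward pass: dV is B x d. Returns parameter gradients (same shapes as
# par).
.nn_backward <- function(par, spec, cache, dV) {
  L <- spec$input_length
  act <- spec$activation
  B <- nrow(dV)
  dFmat <- crossprod(par$Wfc, t(dV))                  # (C3*L) x B
  dWfc <- t(dV) %*% t(cache$Fmat)
  dbfc <- colSums(dV)
  dz3 <- matrix(dFmat, nrow = nrow(cache$z3), ncol = B * L)
  da3 <- if (act) dz3 * (cache$a3 > 0) else dz3
  bk3 <- .conv5_backward(da3, par$W3, cache$c3)
  dz2 <- bk3$dX + da3                                 # skip connection
  da2 <- if (act) dz2 * (cache$c2$out > 0) else dz2
  bk2 <- .conv5_backward(da2, par$W2, cache$c2)
  dz1 <- bk2$dX
  da1 <- if (act) dz1 * (cache$a1 > 0) else dz1
  dW1 <- tcrossprod(da1, cache$X)
  db1 <- rowSums(da1)
  list(W1 = dW1, b1 = db1, W2 = bk2$dW, b2 = bk2$db,
       W3 = bk3$dW, b3 = bk3$db, Wfc = dWfc, bfc = dbfc)
}

#' Encoder forward pass for a single one-hot matrix
#'
#' @param model an [encoder_init()] model.
#' @param onehot a 4 x L one-hot matrix (see [encode_one_hot()]).
#' @return numeric vector of length `embed_dim` (pre-exponential-map).
#' @export
encoder_forward <- function(model, onehot) {
  stopifnot(inherits(model, "embedding_model"))
  if (!is.matrix(onehot) || nrow(onehot) != 4L)
    stop("onehot must be a 4 x L matrix")
  if (ncol(onehot) != model$spec$input_length)
    stop(sprintf("input length %d does not match the model's %d",
                 ncol(onehot), model$spec$input_length))
  drop(.nn_forward(model$par, model$spec, onehot, 1L)$V)
}

# Encoder outputs for a set of alignment rows: n x d matrix of tangent
# vectors (loid/poincare) or points (euclidean).
.encoder_outputs <- function(model, aln, ids = aln$ids) {
  if (aln$length != model$spec$input_length)
    stop(sprintf("alignment length %d does not match the model's input length %d",
                 aln$length, model$spec$input_length))
  X <- .encode_batch(aln, ids)
  V <- .nn_forward(model$par, model$spec, X, length(ids))$V
  rownames(V) <- ids
  V
}

#' Embed aligned sequences into the model's geometry
#'
#' Runs the encoder and composes it with the exponential map of the model's
#' geometry at unit curvature: 'Loid points for `loid` mode, Poincare-ball
#' points for `poincare` mode, and the raw encoder outputs in `euclidean`
#' mode.
#'
#' @param model an `embedding_model`.
#' @param aln an [alignment()] with the model's input length.
#' @return a matrix with one embedded point per row (d + 1 columns in loid
#'   mode, d otherwise), rownames = sequence ids.
#' @export
embed_sequences <- function(model, aln) {
  stopifnot(inherits(model, "embedding_model"))
  V <- .encoder_outputs(model, aln)
  switch(model$mode$mode,
    loid = {
      P <- t(apply(V, 1, loid_exp, C = -1))
      rownames(P) <- rownames(V)
      P
    },
    poincare = {
      P <- t(apply(V, 1, poincare_exp0, C = -1))
      rownames(P) <- rownames(V)
      P
    },
    euclidean = V)
}

# ---- checkpointing --------------------------------------------------------

#' Save / load an embedding model checkpoint
#'
#' The checkpoint holds the encoder parameters, the geometry mode (model,
#' scale, dimension), the tree-distance normalization factor, the encoder
#' spec, the backbone leaf ordering and a format version; round-trip
#' stable.
#'
#' @param model an `embedding_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "embedding_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "embedding_model") || is.null(model$version))
    stop("not an embedding model checkpoint: ", path)
  model
}
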