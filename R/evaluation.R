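# Distortion metrics, outlier accounting, the small/large distance split
# and batching diagnostics.

#' Weighted squared error of a distance estimate
#'
#' `(d_est - d_true)^2 / d_true^2 = (d_est/d_true - 1)^2`: the squared
#' relative deviation of an estimated distance from the true tree
#' distance. Vectorized.
#'
#' @param d_est estimated distance(s).
#' @param d_true true tree distance(s), strictly positive.
#' @return nonnegative weighted squared error(s).
#' @export
weighted_se <- function(d_est, d_true) {
  if (any(d_true <= 0)) stop("d_true must be positive")
  (d_est / d_true - 1)^2
}

#' Distortion report for a set of estimated distances
#'
#' Computes the plain mean squared error, the weighted (inverse squared
#' tree distance) MSE, the weighted median SE, and the fraction of
#' outliers -- pairs whose weighted SE is strictly greater than
#' `outlier_threshold`. For square symmetric inputs only the distinct
#' off-diagonal pairs are evaluated; for rectangular (query x backbone)
#' inputs, all entries.
#'
#' @param d_est matrix (or vector) of estimated distances.
#' @param d_true matching matrix (or vector) of true distances, positive
#'   on evaluated pairs.
#' @param outlier_threshold weighted-SE outlier cutoff (default 100,
#'   strict inequality).
#' @param drop_outliers_for_mse exclude outlier pairs from the weighted
#'   MSE (default FALSE); the outlier fraction and median always use all
#'   pairs.
#' @return a list of class `distortion_report`: `mse`, `weighted_mse`,
#'   `weighted_median_se`, `n_pairs`, `outlier_fraction`.
#' @export
distortion_report <- function(d_est, d_true, outlier_threshold = 100,
                              drop_outliers_for_mse = FALSE) {
  if (is.matrix(d_est)) {
    if (!all(dim(d_est) == dim(d_true)))
      stop("d_est and d_true have different shapes")
    if (nrow(d_est) == ncol(d_est) &&
        isTRUE(all.equal(unname(d_est), unname(t(d_est)))) &&
        isTRUE(all.equal(unname(d_true), unname(t(d_true))))) {
      keep <- upper.tri(d_est)
      d_est <- d_est[keep]; d_true <- d_true[keep]
    } else {
      d_est <- as.vector(d_est); d_true <- as.vector(d_true)
    }
  }
  if (length(d_est) != length(d_true))
    stop("d_est and d_true have different lengths")
  if (length(d_est) == 0) stop("no distance pairs to evaluate")
  if (any(d_true <= 0)) stop("d_true must be positive on evaluated pairs")
  wse <- weighted_se(d_est, d_true)
  is_out <- wse > outlier_threshold
  keep_mse <- if (drop_outliers_for_mse) !is_out else rep(TRUE, length(wse))
  structure(list(
    mse = mean((d_est - d_true)^2),
    weighted_mse = mean(wse[keep_mse]),
    weighted_median_se = stats::median(wse),
    n_pairs = length(wse),
    outlier_fraction = mean(is_out)
  ), class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<distortion_report> %d pairs\n",
    "  MSE               %.6g\n",
    "  weighted MSE      %.6g\n",
    "  weighted median SE %.6g\n",
    "  outlier fraction  %.4g\n"),
    x$n_pairs, x$mse, x$weighted_mse, x$weighted_median_se,
    x$outlier_fraction))
  invisible(x)
}

#' Write a distortion report as TSV
#'
#' @param report a [distortion_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distortion_report <- function(report, path) {
  df <- data.frame(metric = c("mse", "weighted_mse", "weighted_median_se",
                              "n_pairs", "outlier_fraction"),
                   value = c(report$mse, report$weighted_mse,
                             report$weighted_median_se, report$n_pairs,
                             report$outlier_fraction))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split pairs into the k smallest distances per taxon vs the rest
#'
#' Distance-based placement uses only the few smallest distances per
#' query, so distortion is examined separately on each taxon's `k`
#' smallest true distances ("small" pairs) and on everything else. For a
#' rectangular query x backbone table the split is per query row; for a
#' square symmetric matrix a pair is small if it is among the `k` smallest
#' for either endpoint. Ties are broken lexicographically by the partner
#' id.
#'
#' @param d_true matrix of true tree distances (square symmetric, or
#'   query x backbone).
#' @param k neighborhood size (default 5).
#' @return `list(small, large)`: two-column data.frames of pair labels
#'   (`row`, `col`) partitioning the evaluated pairs.
#' @export
split_small_large <- function(d_true, k = 5L) {
  stopifnot(is.matrix(d_true), k >= 1)
  rn <- rownames(d_true) %||% as.character(seq_len(nrow(d_true)))
  cn <- colnames(d_true) %||% as.character(seq_len(ncol(d_true)))
  square <- nrow(d_true) == ncol(d_true) && identical(rn, cn)
  small <- matrix(FALSE, nrow(d_true), ncol(d_true))
  for (i in seq_len(nrow(d_true))) {
    d <- d_true[i, ]
    cand <- setdiff(seq_along(d), if (square) i else integer(0))
    ord <- cand[order(d[cand], cn[cand])]
    small[i, ord[seq_len(min(k, length(ord)))]] <- TRUE
  }
  if (square) {
    small <- small | t(small)        # small for either endpoint
    keep <- upper.tri(d_true)
  } else {
    keep <- matrix(TRUE, nrow(d_true), ncol(d_true))
  }
  idx_s <- which(small & keep, arr.ind = TRUE)
  idx_l <- which(!small & keep, arr.ind = TRUE)
  pairdf <- function(idx) data.frame(row = rn[idx[, 1]], col = cn[idx[, 2]],
                                     stringsAsFactors = FALSE)
  list(small = pairdf(idx_s), large = pairdf(idx_l))
}

#' Probability a fixed pair is never co-batched
#'
#' With `N` taxa randomly partitioned into batches of size `B` each epoch,
#' the standard approximation for the probability that a fixed pair never
#' shares a batch over `epochs` epochs is `(1 - B/N)^epochs` (per-epoch
#' co-occurrence probability approximated by `B/N`). For 7800 taxa,
#' batches of 32 and 1000 epochs this gives 1.6%.
#'
#' @param N number of taxa.
#' @param B batch size, `2 <= B <= N`.
#' @param epochs number of epochs (>= 0).
#' @return probability in `[0, 1]`.
#' @export
cobatch_never_probability <- function(N, B, epochs) {
  stopifnot(B >= 2, B <= N, epochs >= 0)
  (1 - B / N)^epochs
}

#' @describeIn cobatch_never_probability the exact version: the per-epoch
#'   co-occurrence probability of a fixed pair under a uniform random
#'   partition into `floor(N/B)` batches of `B` plus a remainder batch is
#'   `(n_full * C(B,2) + C(r,2)) / C(N,2)`; never-probability is its
#'   complement to the `epochs` power.
#' @export
cobatch_never_probability_exact <- function(N, B, epochs) {
  stopifnot(B >= 2, B <= N, epochs >= 0)
  n_full <- N %/% B
  r <- N %% B
  p_same <- (n_full * choose(B, 2) + choose(r, 2)) / choose(N, 2)
  (1 - p_same)^epochs
}
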