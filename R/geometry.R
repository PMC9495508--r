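# Closed-form hyperbolic and Euclidean distance functions, exponential maps,
# and the curvature/scale reparameterization.
#
# All hyperbolic computation in this package happens at unit curvature
# (C = -1); an arbitrary curvature C < 0 is represented by the scale
# s = 1/sqrt(-C) which multiplies unit-curvature distances. The functions
# below nevertheless accept a general C so that the reparameterization
# identity can be exercised directly.

# acosh arguments can fall below 1 by round-off for (near-)identical points;
# arguments below 1 by more than this tolerance indicate an invariant
# violation and raise an error.
.ACOSH_TOL <- 1e-9

# acosh with round-off guard: arguments within 1e-12 of 1 (numerically
# coincident points) map to distance exactly 0.
.acosh0 <- function(u) {
  d <- acosh(pmax(u, 1))
  d[u - 1 < 1e-12] <- 0
  d
}

.safe_acosh <- function(u) {
  if (any(u < 1 - .ACOSH_TOL)) {
    stop("acosh argument ", format(min(u)), " below 1 beyond tolerance; ",
         "input points violate the hyperbolic domain constraints")
  }
  .acosh0(u)
}

#' Geometry mode descriptor
#'
#' Bundles the embedding geometry (`"loid"`, `"poincare"` or `"euclidean"`),
#' the scale factor `s` and the embedding dimension `d`. In the hyperbolic
#' modes `s = 1/sqrt(-C)` for curvature `C < 0`, and all internal computation
#' is done at unit curvature with `s` multiplying distances. In euclidean
#' mode the "distance" is the squared Euclidean distance (the convention of
#' Euclidean sequence embedding), again multiplied by `s`.
#'
#' @param mode one of `"loid"`, `"poincare"`, `"euclidean"`.
#' @param scale positive scale factor `s`.
#' @param dim embedding dimension `d` (>= 2); 'Loid points carry `d + 1`
#'   coordinates.
#' @return an object of class `geometry_mode`.
#' @export
geometry_mode <- function(mode = c("loid", "poincare", "euclidean"),
                          scale = 1, dim = 2L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  dim <- as.integer(dim)
  if (dim < 2L) stop("embedding dimension must be at least 2")
  structure(list(mode = mode, scale = scale, dim = dim),
            class = "geometry_mode")
}

#' @export
print.geometry_mode <- function(x, ...) {
  cat(sprintf("<geometry_mode> %s, d = %d, s = %g (curvature %g)\n",
              x$mode, x$dim, x$scale,
              if (x$mode == "euclidean") 0 else -1 / x$scale^2))
  invisible(x)
}

.check_curvature <- function(C) {
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C))
  if (C >= 0) stop("curvature C must be negative, got ", C)
  C
}

#' Poincare ball distance
#'
#' Geodesic distance between two points of the d-dimensional Poincare ball
#' of curvature `C < 0`, the ball of squared radius `-1/C`.
#'
#' @param x,y numeric vectors of equal length with `-C * ||.||^2 < 1`.
#' @param C negative curvature (default -1).
#' @return nonnegative distance.
#' @export
poincare_distance <- function(x, y, C = -1) {
  .check_curvature(C)
  if (length(x) != length(y)) stop("points have mismatched dimensions")
  nx <- sum(x^2); ny <- sum(y^2)
  if (-C * nx >= 1 || -C * ny >= 1) {
    stop(sprintf(
      "point on or outside the Poincare domain: -C*||x||^2 = %.6g, -C*||y||^2 = %.6g (must be < 1)",
      -C * nx, -C * ny))
  }
  u <- 1 - 2 * C * sum((x - y)^2) / ((1 + C * nx) * (1 + C * ny))
  .safe_acosh(u) / sqrt(-C)
}

#' 'Loid (hyperboloid / Lorentz) model distance
#'
#' Distance between two points on the upper sheet of the hyperboloid
#' `x' H x = 1/C`, `x[1] > 0`, with `H = diag(-1, 1, ..., 1)`.
#'
#' @param x,y numeric vectors of length `d + 1` satisfying the hyperboloid
#'   constraint at curvature `C`.
#' @param C negative curvature (default -1).
#' @param check validate the hyperboloid constraint (default TRUE).
#' @return nonnegative distance.
#' @export
loid_distance <- function(x, y, C = -1, check = TRUE) {
  .check_curvature(C)
  if (length(x) != length(y)) stop("points have mismatched dimensions")
  if (check) {
    for (p in list(x, y)) {
      q <- -p[1]^2 + sum(p[-1]^2)
      if (abs(q - 1 / C) > 1e-6 * max(1, abs(1 / C)) || p[1] <= 0) {
        stop(sprintf("point violates the hyperboloid constraint: x'Hx = %.8g, expected %.8g",
                     q, 1 / C))
      }
    }
  }
  bilin <- -x[1] * y[1] + sum(x[-1] * y[-1])  # x' H y
  .safe_acosh(C * bilin) / sqrt(-C)
}

#' Squared Euclidean distance
#'
#' The Euclidean-mode "distance" used when matching tree distances with
#' squared distances of embedded points. Note this is not a metric (no
#' triangle inequality); it is the quantity the Euclidean embedding is
#' trained to match to tree distances.
#'
#' @param x,y numeric vectors of equal length.
#' @return `sum((x - y)^2)`.
#' @export
euclidean_sq_distance <- function(x, y) {
  if (length(x) != length(y)) stop("points have mismatched dimensions")
  sum((x - y)^2)
}

#' Exponential map at the origin of the Poincare ball
#'
#' Maps a tangent vector `v` in R^d to the curvature-`C` Poincare ball:
#' `tanh(sqrt(-C)||v||) / (sqrt(-C)||v||) * v`. Total function; `v = 0`
#' maps to the origin.
#'
#' @param v numeric vector.
#' @param C negative curvature (default -1).
#' @return a point strictly inside the ball of squared radius `-1/C`.
#' @export
poincare_exp0 <- function(v, C = -1) {
  .check_curvature(C)
  r <- sqrt(sum(v^2)) * sqrt(-C)
  if (r < 1e-12) return(v)  # tanh(r)/r -> 1
  tanh(r) / r * v
}

#' Exponential map at the base point of the 'Loid model
#'
#' Maps a tangent vector `v` in R^d to the hyperboloid:
#' `cosh(sqrt(-C)||v||) p0 + sinh(sqrt(-C)||v||)/||v|| (0, v)` with base
#' point `p0 = e1 / sqrt(-C)`. At `C = -1` the output satisfies the
#' hyperboloid constraint exactly (up to round-off).
#'
#' @param v numeric vector of length d.
#' @param C negative curvature (default -1).
#' @return numeric vector of length `d + 1`.
#' @export
loid_exp <- function(v, C = -1) {
  .check_curvature(C)
  nv <- sqrt(sum(v^2))
  r <- sqrt(-C) * nv
  p0 <- c(1 / sqrt(-C), rep(0, length(v)))
  if (nv < 1e-12) return(p0)
  cosh(r) * p0 + c(0, sinh(r) / nv * v)
}

#' Rescale a curvature-C Poincare point to the unit ball
#'
#' The normalization `x' = sqrt(-C) x` mapping the curvature-`C` ball onto
#' the unit-curvature ball, under which
#' `d_C(x, y) = (1/sqrt(-C)) d_{-1}(x', y')`.
#'
#' @param x numeric vector with `-C ||x||^2 < 1`.
#' @param C negative curvature.
#' @return the rescaled point, inside the unit ball.
#' @export
rescale_to_unit_ball <- function(x, C) {
  .check_curvature(C)
  if (-C * sum(x^2) >= 1) stop("point outside the curvature-C Poincare domain")
  sqrt(-C) * x
}

#' Scaled distance in a geometry mode
#'
#' `s` times the unit-curvature distance of the active mode; in euclidean
#' mode `s` times the squared Euclidean distance.
#'
#' @param x,y points valid in the unit-curvature domain of `mode`.
#' @param mode a [geometry_mode()].
#' @return nonnegative scaled distance.
#' @export
scaled_distance <- function(x, y, mode) {
  stopifnot(inherits(mode, "geometry_mode"))
  d <- switch(mode$mode,
    loid      = loid_distance(x, y, -1),
    poincare  = poincare_distance(x, y, -1),
    euclidean = euclidean_sq_distance(x, y))
  mode$scale * d
}

#' Stereographic projection from the 'Loid model to the Poincare ball
#'
#' Maps a unit-curvature hyperboloid point to the unit Poincare ball by
#' `x[-1] / (1 + x[1])`; an isometry between the two models.
#'
#' @param x numeric vector of length `d + 1` on the unit-curvature
#'   hyperboloid.
#' @return a point inside the unit ball.
#' @export
loid_to_poincare <- function(x) {
  q <- -x[1]^2 + sum(x[-1]^2)
  if (abs(q + 1) > 1e-6 || x[1] <= 0) {
    stop("not a valid unit-curvature 'Loid point")
  }
  x[-1] / (1 + x[1])
}

#' Maximum representable unit-curvature distance at p decimal digits
#'
#' The largest unit-curvature Poincare distance among points whose squared
#' norm is at most `1 - 10^-p`:
#' `2 acosh(1 + 2 (1 - 10^-p) / 10^-p)`, which grows almost linearly in `p`
#' (approximately `4 log 2 + 2 p log 10`). Motivates normalizing tree
#' distances to at most 1 before training rather than using extended
#' precision.
#'
#' @param p positive integer, the number of decimal digits separating the
#'   points' squared norms from 1.
#' @return the distance bound (vectorized over `p`).
#' @export
max_distance_bound <- function(p) {
  stopifnot(all(p >= 1))
  eps <- 10^(-p)
  2 * acosh(1 + 2 * (1 - eps) / eps)
}

# ---- internal vectorized pairwise machinery -------------------------------

# Row-wise unit-curvature pairwise distances between selected pairs.
# V: n x d matrix of *pre-exponential-map* encoder outputs (tangent vectors
# for hyperbolic modes, points themselves in euclidean mode).
# i, j: integer vectors of equal length indexing rows of V.
# Returns the vector of unit-curvature distances d(phi(v_i), phi(v_j)).
.pair_unit_distances <- function(V, i, j, mode) {
  switch(mode,
    loid = {
      r <- sqrt(rowSums(V^2))
      g <- ifelse(r < 1e-8, 1 + r^2 / 6, sinh(r) / r)   # sinh(r)/r
      S <- rowSums(V[i, , drop = FALSE] * V[j, , drop = FALSE])
      u <- cosh(r[i]) * cosh(r[j]) - g[i] * g[j] * S
      .acosh0(u)
    },
    poincare = {
      r <- sqrt(rowSums(V^2))
      g <- ifelse(r < 1e-8, 1 - r^2 / 3, tanh(r) / r)   # tanh(r)/r
      X <- V * g
      nx <- rowSums(X^2)
      D2 <- rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2)
      u <- 1 + 2 * D2 / ((1 - nx[i]) * (1 - nx[j]))
      .acosh0(u)
    },
    euclidean = rowSums((V[i, , drop = FALSE] - V[j, , drop = FALSE])^2)
  )
}
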