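# Small shared helpers: RNG scoping, quaternions, spherical quadrature,
# Kabsch superposition. All lengths in nm unless a function says otherwise.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators are pure
#' functions of their `seed` argument and never disturb a session's stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Quaternion convention is (w, x, y, z) with `w` the scalar part; the
#' returned matrix acts on column vectors, so row-wise coordinate matrices
#' rotate as `coords %*% t(R)`.
#'
#' @param q numeric length-4 unit quaternion
#' @return 3x3 rotation matrix
#' @export
quat_to_mat <- function(q) {
  stopifnot(length(q) == 4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Geodesic distance between two rotations, in degrees
#'
#' Distance on SO(3): the magnitude of the rotation carrying one frame to
#' the other, `2*acos(|<q1,q2>|)`, insensitive to the quaternion double
#' cover.
#'
#' @param q1,q2 unit quaternions (w, x, y, z)
#' @return angle in degrees in [0, 180]
#' @export
quat_geodesic_deg <- function(q1, q2) {
  d <- abs(sum(q1 * q2))
  d <- min(1, max(-1, d))
  2 * acos(d) * 180 / pi
}

#' Fibonacci lattice on the unit sphere
#'
#' Deterministic quasi-uniform directions; the first point is the +z pole so
#' downstream rotation grids contain the identity exactly.
#'
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @keywords internal
fibonacci_sphere <- function(n) {
  if (n == 1) return(matrix(c(0, 0, 1), 1, 3))
  i <- seq_len(n) - 1
  # cos(theta) descends from exactly 1 (pole) to -1 + 1/n
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' between matched point sets. Points are rows.
#'
#' @param mobile n x 3 matrix to move
#' @param ref n x 3 reference matrix
#' @return list with `rotation` (3x3, applied as `centered %*% rotation`),
#'   `mobile_center`, `ref_center`, and `rmsd` in the input units
#' @export
kabsch_fit <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (!all(dim(mobile) == dim(ref))) stop("point count mismatch in kabsch_fit")
  if (nrow(mobile) < 3) stop("kabsch_fit needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- A %*% R
  list(rotation = R, mobile_center = cm, ref_center = cr,
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

#' Apply a Kabsch fit to arbitrary coordinates
#'
#' @param coords n x 3 matrix in the mobile frame
#' @param fit result of [kabsch_fit()]
#' @return transformed n x 3 matrix in the reference frame
#' @export
apply_kabsch <- function(coords, fit) {
  sweep(sweep(as.matrix(coords), 2, fit$mobile_center) %*% fit$rotation,
        2, fit$ref_center, `+`)
}

# all-pairs squared distances between two row-wise coordinate sets
cross_dist2 <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
}
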