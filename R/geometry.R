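## Rotation and triangle geometry primitives shared across the pipeline.
##
## Convention: right-handed frame, x right / y up / z toward the viewer.
## Orientations are intrinsic z-x-y Euler angles in degrees: yaw about z,
## then pitch about the (new) x axis, then roll about the (new) y axis.
## The image plane is (x, y); projection is orthographic along z.

.deg2rad <- pi / 180

#' Rotation matrix from yaw/pitch/roll
#'
#' Builds the 3x3 rotation matrix for intrinsic z-x-y Euler angles
#' (yaw about z, pitch about x, roll about y), all in degrees.
#'
#' @param yaw,pitch,roll Angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
#' @examples
#' rotation_matrix(90, 0, 0) %*% c(1, 0, 0)  # maps x onto y
rotation_matrix <- function(yaw, pitch, roll) {
  c1 <- cos(yaw * .deg2rad);   s1 <- sin(yaw * .deg2rad)
  c2 <- cos(pitch * .deg2rad); s2 <- sin(pitch * .deg2rad)
  c3 <- cos(roll * .deg2rad);  s3 <- sin(roll * .deg2rad)
  ## Rz(yaw) %*% Rx(pitch) %*% Ry(roll), expanded
  matrix(c(
    c1 * c3 - s1 * s2 * s3, -s1 * c2, c1 * s3 + s1 * s2 * c3,
    s1 * c3 + c1 * s2 * s3,  c1 * c2, s1 * s3 - c1 * s2 * c3,
    -c2 * s3,                s2,      c2 * c3
  ), nrow = 3, byrow = TRUE)
}

## Inverse of rotation_matrix: recover (yaw, pitch, roll) in degrees from a
## rotation matrix, using the z-x-y intrinsic convention.
.euler_from_matrix <- function(R) {
  pitch <- asin(max(-1, min(1, R[3, 2])))
  roll  <- atan2(-R[3, 1], R[3, 3])
  yaw   <- atan2(-R[1, 2], R[2, 2])
  c(yaw = yaw, pitch = pitch, roll = roll) / .deg2rad
}

#' Vertices of a centered equilateral triangle
#'
#' Returns the three vertices of an equilateral triangle of the given side
#' length, centered at the origin in the z = 0 plane, one vertex on the +y
#' axis. The circumradius is `side / sqrt(3)`.
#'
#' @param side Side length (nm).
#' @return A 3x3 matrix (rows = vertices, columns = x, y, z) in nm.
#' @export
equilateral_vertices <- function(side) {
  stopifnot(is.finite(side), side >= 0)
  a <- side / sqrt(3)
  matrix(c(
    0, a, 0,
    -a * sqrt(3) / 2, -a / 2, 0,
    a * sqrt(3) / 2, -a / 2, 0
  ), nrow = 3, byrow = TRUE,
  dimnames = list(NULL, c("x", "y", "z")))
}

#' Orthographic projection of rotated vertices
#'
#' Applies a rotation to a set of 3D points and projects the result onto the
#' image (x, y) plane. The centroid of the input is preserved.
#'
#' @param vertices Nx3 matrix of 3D points (nm).
#' @param yaw,pitch,roll Euler angles in degrees (see [rotation_matrix()]).
#' @return An Nx2 matrix of projected (x, y) positions in nm.
#' @export
project_vertices <- function(vertices, yaw = 0, pitch = 0, roll = 0) {
  R <- rotation_matrix(yaw, pitch, roll)
  out <- vertices %*% t(R[1:2, , drop = FALSE])
  colnames(out) <- c("x", "y")
  out
}

#' Fold an angle into [0, 90] degrees
#'
#' Orthographic projection is unchanged by view inversion, so out-of-plane
#' angles are only identified up to a four-fold symmetry; this maps any angle
#' to its representative in \[0, 90\] degrees.
#'
#' @param a Angle(s) in degrees.
#' @return Angle(s) in \[0, 90\].
#' @export
fold_angle <- function(a) {
  a <- abs(a) %% 180
  ifelse(a > 90, 180 - a, a)
}

## Pairwise distances between the three rows of a 3x2 (or 3x3) matrix,
## returned as c(d12, d13, d23).
.tri_dists <- function(v) {
  c(sqrt(sum((v[1, ] - v[2, ])^2)),
    sqrt(sum((v[1, ] - v[3, ])^2)),
    sqrt(sum((v[2, ] - v[3, ])^2)))
}

## Uniform random rotations via Shoemake's quaternion method; returns a list
## of 3x3 matrices, or a 3n x 3 row-bound matrix when flat = TRUE.
.random_rotations <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  q0 <- sqrt(1 - u1) * sin(2 * pi * u2)
  q1 <- sqrt(1 - u1) * cos(2 * pi * u2)
  q2 <- sqrt(u1) * sin(2 * pi * u3)
  q3 <- sqrt(u1) * cos(2 * pi * u3)
  list(q0 = q0, q1 = q1, q2 = q2, q3 = q3)
}

.quat_to_matrix <- function(q0, q1, q2, q3) {
  matrix(c(
    1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)
  ), nrow = 3, byrow = TRUE)
}

#' Maximum projected side lengths of a randomly oriented equilateral triangle
#'
#' Draws uniformly random 3D orientations and returns, for each, the largest
#' of the three projected pairwise distances of an equilateral triangle of
#' side `side`. Used for the projection-bound property: the value always lies
#' in \[sqrt(3)/2 * side, side\].
#'
#' Vectorized over orientations (quaternion sampling), so large n is cheap.
#'
#' @param n Number of orientations.
#' @param side Side length (nm).
#' @param seed Optional RNG seed.
#' @return Numeric vector of n maximum projected side lengths (nm).
#' @export
max_side_uniform <- function(n, side = 1, seed = NULL) {
  .with_seed(seed, {
    q <- .random_rotations(n)
    v <- equilateral_vertices(side)
    ## projected vertex k = (row1 . v_k, row2 . v_k) of the rotation matrix
    r11 <- 1 - 2 * (q$q2^2 + q$q3^2)
    r12 <- 2 * (q$q1 * q$q2 - q$q0 * q$q3)
    r21 <- 2 * (q$q1 * q$q2 + q$q0 * q$q3)
    r22 <- 1 - 2 * (q$q1^2 + q$q3^2)
    ## vertices have z = 0, so only the first two columns matter
    px <- sapply(1:3, function(k) r11 * v[k, 1] + r12 * v[k, 2])
    py <- sapply(1:3, function(k) r21 * v[k, 1] + r22 * v[k, 2])
    d12 <- sqrt((px[, 1] - px[, 2])^2 + (py[, 1] - py[, 2])^2)
    d13 <- sqrt((px[, 1] - px[, 3])^2 + (py[, 1] - py[, 3])^2)
    d23 <- sqrt((px[, 2] - px[, 3])^2 + (py[, 2] - py[, 3])^2)
    pmax(d12, d13, d23)
  })
}

#' Brute-force view-direction oracle for the projected max side
#'
#' Independent check of the projection bound: scans a dense, equal-area grid
#' of view directions on the sphere (uniform in cos of the polar angle) and
#' computes the maximum projected side of an equilateral triangle viewed
#' along each direction. Because grid cells carry equal solid angle, the
#' returned values can be compared distributionally (e.g. by a KS statistic)
#' with draws from uniformly random orientations. Free of any
#' orientation-sampling code, so it serves as an independent oracle for
#' [max_side_uniform()].
#'
#' @param side Side length (nm).
#' @param n_theta,n_phi Grid resolution in (cosine of) polar and azimuthal angle.
#' @return Numeric vector of maximum projected side lengths over the grid.
#' @export
max_side_view_grid <- function(side = 1, n_theta = 90, n_phi = 180) {
  v <- equilateral_vertices(side)
  ## midpoints of equal-width cos(theta) bins -> equal-area latitude rows
  ct <- seq(-1, 1, length.out = n_theta + 1)
  ct <- (ct[-1] + ct[-(n_theta + 1)]) / 2
  theta <- acos(ct)
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  g <- expand.grid(theta = theta, phi = phi)
  ## view direction n; project points onto the plane orthogonal to n and
  ## measure distances there (orthographic projection along n)
  nx <- sin(g$theta) * cos(g$phi)
  ny <- sin(g$theta) * sin(g$phi)
  nz <- cos(g$theta)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  dmat <- sapply(pairs, function(ij) {
    e <- v[ij[1], ] - v[ij[2], ]
    dot <- nx * e[1] + ny * e[2] + nz * e[3]
    sqrt(sum(e^2) - dot^2)
  })
  apply(dmat, 1, max)
}

## Run code with a temporary RNG state when seed is non-NULL; restores the
## caller's .Random.seed afterwards so seeded helpers compose predictably.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
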