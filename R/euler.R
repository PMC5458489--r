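# Euler angle utilities.
#
# Convention used throughout the package: ZXZ intrinsic, ACTIVE rotations,
# angles in degrees. A triplet (a, b, c) denotes R = Rz(a) %*% Rx(b) %*% Rz(c);
# applying R to a volume moves density (the template is rotated, the grid is
# fixed). This matches the (tdrot, tilt, narot) vocabulary familiar from
# subtomogram-averaging practice. The convention is a declared one: it is
# fixed here and used consistently by every operator.

rot_z <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  a <- deg2rad(deg); ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

#' Rotation matrix of a ZXZ Euler triplet
#'
#' @param euler numeric length-3 vector of angles in degrees (ZXZ intrinsic,
#'   active).
#' @return a 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler) {
  stopifnot(is.numeric(euler), length(euler) == 3)
  rot_z(euler[1]) %*% rot_x(euler[2]) %*% rot_z(euler[3])
}

#' Euler triplet of a rotation matrix
#'
#' Inverse of [euler_to_matrix()]. At gimbal lock (tilt of 0 or 180 degrees)
#' the first angle absorbs the full in-plane rotation and the third is set
#' to 0.
#'
#' @param R a 3x3 rotation matrix.
#' @return numeric length-3 Euler triplet in degrees.
#' @export
matrix_to_euler <- function(R) {
  cb <- max(-1, min(1, R[3, 3]))
  b <- rad2deg(acos(cb))
  sb <- sqrt(max(0, 1 - cb^2))
  if (sb > 1e-9) {
    a <- rad2deg(atan2(R[1, 3], -R[2, 3]))
    c <- rad2deg(atan2(R[3, 1], R[3, 2]))
  } else {
    # R reduces to Rz(a) (b ~ 0) or Rz(a) Rx(180) (b ~ 180)
    a <- rad2deg(atan2(R[2, 1], R[1, 1]))
    c <- 0
  }
  c(a, b, c)
}

#' Inverse of an Euler triplet
#'
#' For ZXZ triplets the inverse rotation is the reversed, negated triplet.
#'
#' @inheritParams euler_to_matrix
#' @return the Euler triplet of the inverse rotation.
#' @export
euler_inverse <- function(euler) c(-euler[3], -euler[2], -euler[1])

#' Compose two Euler triplets
#'
#' Returns the triplet of `R(first) %*% R(second)`, i.e. `second` applied
#' first under the active convention.
#'
#' @param first,second Euler triplets in degrees.
#' @return composed Euler triplet.
#' @export
euler_compose <- function(first, second)
  matrix_to_euler(euler_to_matrix(first) %*% euler_to_matrix(second))

#' Geodesic angle between two rotations
#'
#' The rotation angle (degrees, in `[0, 180]`) of the relative rotation
#' between two Euler triplets — the natural error metric for recovered
#' orientations.
#'
#' @param e1,e2 Euler triplets in degrees (ZXZ intrinsic, active).
#' @return angle in degrees.
#' @export
rotation_between <- function(e1, e2) {
  R <- crossprod(euler_to_matrix(e1), euler_to_matrix(e2))
  rad2deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
}

rotation_distance <- rotation_between

# Direction (unit vector) obtained by rotating the z-axis.
euler_direction <- function(euler) as.vector(euler_to_matrix(euler)[, 3])

angle_between <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  rad2deg(acos(max(-1, min(1, cu))))
}

# Unit quaternion of a rotation matrix, canonical sign (first non-zero
# component positive); used for duplicate removal in angular grids.
matrix_to_quat <- function(R) {
  t <- sum(diag(R))
  if (t > 0) {
    s <- sqrt(t + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q <- q / sqrt(sum(q^2))
  nz <- which(abs(q) > 1e-9)[1]
  if (length(nz) && q[nz] < 0) q <- -q
  q
}
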